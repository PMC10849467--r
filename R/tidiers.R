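# broom-style tidiers for fitted objects and evaluation reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pre-training fit
#'
#' @param x A `grf_pretrain_fit` from [pretrain_ssl()] or
#'   [pretrain_supervised()].
#' @param ... Unused.
#' @return Tibble with `step` and `loss`.
#' @export
tidy.grf_pretrain_fit <- function(x, ...) {
  tibble::tibble(step = seq_along(x$loss_history), loss = x$loss_history)
}

#' @rdname tidy.grf_pretrain_fit
#' @export
glance.grf_pretrain_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective,
                 n_steps = length(x$loss_history),
                 initial_loss = x$loss_history[1],
                 final_loss = utils::tail(x$loss_history, 1),
                 n_parameters = sum(vapply(x$state$params, length, 1L)))
}

#' Tidy a fine-tuning fit
#'
#' @param x A `grf_finetune_fit` from [finetune_two_step()].
#' @param ... Unused.
#' @return Tibble with `step`, `phase` (head / full) and `loss`.
#' @export
tidy.grf_finetune_fit <- function(x, ...) {
  n <- length(x$loss_history)
  n1 <- x$n_step1 %||% (n %/% 2)
  tibble::tibble(step = seq_len(n),
                 phase = rep(c("head", "full"), c(n1, n - n1)),
                 loss = x$loss_history)
}

#' @rdname tidy.grf_finetune_fit
#' @export
glance.grf_finetune_fit <- function(x, ...) {
  tibble::tibble(n_steps = length(x$loss_history),
                 final_loss = utils::tail(x$loss_history, 1),
                 n_present_sensors = length(x$present))
}

#' Tidy an evaluation report
#'
#' @param x A `grf_eval_report` from [evaluate_grf()].
#' @param ... Unused.
#' @return The per-participant, per-axis metric tibble.
#' @export
tidy.grf_eval_report <- function(x, ...) x$per_axis

#' @rdname tidy.grf_eval_report
#' @export
glance.grf_eval_report <- function(x, ...) {
  wide <- x$per_axis |>
    dplyr::group_by(.data$axis) |>
    dplyr::summarise(rho = mean(.data$rho), rmse = mean(.data$rmse)) |>
    tidyr::pivot_wider(names_from = "axis", values_from = c("rho", "rmse"))
  dplyr::bind_cols(wide,
                   tibble::tibble(peak_rho = mean(x$peaks$rho),
                                  peak_rmse = mean(x$peaks$rmse),
                                  peak_rrmse = mean(x$peaks$rrmse)))
}
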