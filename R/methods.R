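# print / tidy / glance / autoplot methods for fitted classifiers.

#' @export
print.envsca_fit <- function(x, ...) {
  cat("<envsca_fit> method:", x$method, "\n")
  cat("  groups:", paste0(x$group_labels, " (n=", x$n_per_group, ")",
                          collapse = ", "), "\n")
  cat("  states:", length(x$state_space), "| reference:", x$ref_state, "\n")
  cat("  frequencies: K =", x$k, "on grid T =", x$t_ref,
      "| bandwidth:", x$bandwidth, "\n")
  if (x$method == "envsca") {
    cat("  kappa:", format(x$kappa),
        if (!is.na(x$loo_rate)) paste0("(LOO rate ",
                                       format(round(x$loo_rate, 3)), ")"),
        "\n")
  }
  if (!is.null(x$smb)) {
    cat("  disparity:", x$smb$kind,
        if (!is.null(x$smb$theta)) paste0("(theta = ", x$smb$theta, ")"), "\n")
  }
  invisible(x)
}

#' Tidy the group-level features of a fitted classifier
#'
#' @param x An `envsca_fit`.
#' @param ... Unused.
#' @return Tibble with one row per group and frequency: `group`, `freq`,
#'   `lambda` (group-mean envelope), and `gamma_1 ... gamma_{m-1}`
#'   (group-mean scalings, one column per non-reference category).
#' @method tidy envsca_fit
#' @export
tidy.envsca_fit <- function(x, ...) {
  p <- length(x$categories)
  rows <- lapply(seq_along(x$group_labels), function(j) {
    g <- t(matrix(x$Gamma[, , j], nrow = p))
    colnames(g) <- paste0("gamma_", seq_len(p))
    dplyr::bind_cols(
      tibble::tibble(group = x$group_labels[j], freq = x$freqs,
                     lambda = x$Lambda[j, ]),
      tibble::as_tibble(g))
  })
  dplyr::bind_rows(rows)
}

#' One-row summary of a fitted classifier
#'
#' @inheritParams tidy.envsca_fit
#' @return One-row tibble: method, number of groups, states, frequencies,
#'   smoothing bandwidth, kappa, and training LOO rate (when tuned).
#' @method glance envsca_fit
#' @export
glance.envsca_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_groups = length(x$group_labels),
    n_train = sum(x$n_per_group),
    m = length(x$state_space),
    k = x$k,
    t_ref = x$t_ref,
    bandwidth = x$bandwidth,
    kappa = x$kappa,
    loo_rate = x$loo_rate)
}

#' Plot group-level envelopes and scalings of a fitted classifier
#'
#' Envelope panel: group-mean spectral envelope against frequency.
#' Scaling panels: group-mean optimal scaling per non-reference category.
#'
#' @param object An `envsca_fit`.
#' @param what `"envelope"`, `"scalings"`, or `"both"` (default).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot envsca_fit
#' @export
autoplot.envsca_fit <- function(object,
                                what = c("both", "envelope", "scalings"),
                                ...) {
  what <- match.arg(what)
  td <- tidy.envsca_fit(object)
  long <- tidyr::pivot_longer(td, dplyr::starts_with("gamma_"),
                              names_to = "category", values_to = "value")
  cat_map <- stats::setNames(object$categories,
                             paste0("gamma_", seq_along(object$categories)))
  long$category <- cat_map[long$category]
  env_part <- dplyr::transmute(td, group = .data$group, freq = .data$freq,
                               panel = "envelope", value = .data$lambda)
  sca_part <- dplyr::transmute(long, group = .data$group, freq = .data$freq,
                               panel = paste0("scaling: ", .data$category),
                               value = .data$value)
  plot_data <- switch(what,
                      both = dplyr::bind_rows(env_part, sca_part),
                      envelope = env_part,
                      scalings = sca_part)
  ggplot2::ggplot(plot_data,
                  ggplot2::aes(x = .data$freq, y = .data$value,
                               colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "frequency (cycles per observation)", y = NULL,
                  colour = "group") +
    ggplot2::theme_minimal()
}
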