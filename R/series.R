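# Long-format series handling and indicator (baseline) encoding.
#
# A collection of categorical time series is represented as a long tibble
# with columns series_id, time_index, state. Internally each series is an
# integer vector coding states 1..m in state-space order, with the reference
# category placed implicitly at position m of the encoding.

#' Validate and split a long-format series table
#'
#' @param data Data frame with columns `series_id`, `time_index`, `state`.
#' @param state_space Character vector of the m states, in order. If `NULL`,
#'   inferred as the sorted union of observed states (a message is emitted).
#' @param ref_state Reference category for the baseline encoding; defaults to
#'   the last element of `state_space`.
#'
#' @return A list with elements `series` (named list of character vectors,
#'   sorted by series id), `state_space`, and `ref_state`.
#' @keywords internal
prepare_series <- function(data, state_space = NULL, ref_state = NULL) {
  required <- c("series_id", "time_index", "state")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  data <- dplyr::arrange(dplyr::as_tibble(data), .data$series_id, .data$time_index)
  if (is.null(state_space)) {
    state_space <- sort(unique(as.character(data$state)))
    inform(paste0("state space inferred from data: {",
                  paste(state_space, collapse = ", "), "}"))
  }
  if (anyDuplicated(state_space)) abort("`state_space` contains duplicates")
  if (length(state_space) < 2) abort("state space must contain at least 2 states")
  if (is.null(ref_state)) ref_state <- state_space[length(state_space)]
  if (!ref_state %in% state_space) {
    abort(paste0("reference state '", ref_state, "' is not in the state space"))
  }
  bad <- !as.character(data$state) %in% state_space
  if (any(bad)) {
    i <- which(bad)[1]
    abort(paste0(
      "unknown state '", data$state[i], "' in series '", data$series_id[i],
      "' at time_index ", data$time_index[i],
      "; all categories must be observed in / declared for the state space"))
  }
  series <- split(as.character(data$state), factor(data$series_id,
                                                   levels = unique(data$series_id)))
  idx <- split(data$time_index, factor(data$series_id,
                                       levels = unique(data$series_id)))
  for (id in names(idx)) {
    ti <- idx[[id]]
    if (length(ti) > 1 && any(diff(ti) != 1)) {
      pos <- which(diff(ti) != 1)[1]
      abort(paste0("series '", id, "' has a gap in time_index after value ",
                   ti[pos]))
    }
  }
  list(series = series, state_space = state_space, ref_state = ref_state)
}

# integer coding 1..m with reference mapped to m
code_series <- function(values, state_space, ref_state) {
  ordered_states <- c(setdiff(state_space, ref_state), ref_state)
  match(values, ordered_states)
}

#' Baseline (indicator) encoding of a categorical series
#'
#' Encodes an m-category series as a T x (m-1) matrix of indicators: column
#' l at time t is 1 iff the series is in the l-th non-reference category at
#' time t; observations equal to the reference category give an all-zero row.
#'
#' @param values Character (or factor) vector of observed states, length T.
#' @param state_space Character vector of the m distinct states, in order.
#' @param ref_state The reference category; defaults to the last state.
#'
#' @return A T x (m-1) numeric 0/1 matrix with the non-reference categories
#'   as column names.
#' @examples
#' encode_baseline(c("a", "b", "c", "c"), c("a", "b", "c"))
#' @export
encode_baseline <- function(values, state_space, ref_state = NULL) {
  values <- as.character(values)
  if (anyDuplicated(state_space)) abort("`state_space` contains duplicates")
  m <- length(state_space)
  if (m < 2) abort("state space must contain at least 2 states (m = 1 has no spectrum)")
  if (is.null(ref_state)) ref_state <- state_space[m]
  if (!ref_state %in% state_space) abort("`ref_state` must be in `state_space`")
  bad <- !values %in% state_space
  if (any(bad)) {
    i <- which(bad)[1]
    abort(paste0("unknown state '", values[i], "' at position ", i))
  }
  categories <- setdiff(state_space, ref_state)
  v <- match(values, c(categories, ref_state))
  y <- matrix(0, nrow = length(values), ncol = m - 1,
              dimnames = list(NULL, categories))
  nonref <- which(v < m)
  y[cbind(nonref, v[nonref])] <- 1
  y
}
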