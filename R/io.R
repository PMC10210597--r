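# Readers/writers: long-format series CSV, percentile windowing, and
# lossless JSON model serialization.

#' Read a long-format series CSV
#'
#' The file must have columns `series_id`, `time_index`, `state`
#' (comma-separated, header required; state labels containing commas are
#' rejected rather than quoted). Time indices must be contiguous within
#' each series. Series are returned sorted by id.
#'
#' @param path Path to the CSV file.
#' @inheritParams prepare_series
#' @return A tibble with columns `series_id`, `time_index`, `state` and
#'   attributes `state_space` and `ref_state`.
#' @export
read_series_csv <- function(path, state_space = NULL, ref_state = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  data <- readr::read_csv(path, col_types = readr::cols(
    series_id = readr::col_character(),
    time_index = readr::col_integer(),
    state = readr::col_character(),
    .default = readr::col_character()))
  if (any(grepl(",", data$state)) || any(grepl(",", data$series_id))) {
    abort("state labels / series ids containing commas are not supported")
  }
  prep <- prepare_series(data, state_space, ref_state)
  out <- dplyr::arrange(dplyr::as_tibble(data), .data$series_id,
                        .data$time_index)
  structure(out, state_space = prep$state_space, ref_state = prep$ref_state)
}

#' Write a long-format series table to CSV
#'
#' @param data Data frame with columns `series_id`, `time_index`, `state`.
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_series_csv <- function(data, path) {
  readr::write_csv(dplyr::select(dplyr::as_tibble(data),
                                 dplyr::any_of(c("series_id", "time_index",
                                                 "state", "group"))), path)
  invisible(data)
}

#' Trim each series to a central percentile window
#'
#' Retains, per series of length T, the observations at (0-based) positions
#' `floor(lo * T)` through `ceiling(hi * T) - 1` — a half-open window on
#' the right. The defaults (`lo = 0.4`, `hi = 0.9`) suit overnight
#' sleep-stage recordings, where the central stretch avoids the
#' nonstationary sleep-onset and waking periods and captures most REM
#' sleep; use `lo = 0, hi = 1` for the identity.
#'
#' @param data Long data frame (`series_id`, `time_index`, `state`, ...).
#' @param lo,hi Window percentiles, `0 <= lo < hi <= 1`.
#' @return The trimmed tibble (other columns and attributes preserved).
#' @export
window_by_percentile <- function(data, lo = 0.4, hi = 0.9) {
  if (!(lo >= 0 && lo < hi && hi <= 1)) {
    abort("`lo` and `hi` must satisfy 0 <= lo < hi <= 1")
  }
  out <- dplyr::as_tibble(data) |>
    dplyr::arrange(.data$series_id, .data$time_index) |>
    dplyr::group_by(.data$series_id) |>
    dplyr::filter({
      n <- dplyr::n()
      keep <- seq.int(floor(lo * n) + 1L, ceiling(hi * n))
      if (length(keep) < 4) {
        abort(paste0("window leaves fewer than 4 observations for series '",
                     .data$series_id[1], "'"))
      }
      dplyr::row_number() %in% keep
    }) |>
    dplyr::ungroup()
  structure(out, state_space = attr(data, "state_space"),
            ref_state = attr(data, "ref_state"))
}

# --- model serialization ------------------------------------------------------
# Doubles are written as C99 hexadecimal floating-point literals ("%a"),
# a decimal-free encoding that round-trips binary64 bit-exactly.

enc_num <- function(x) {
  if (is.null(x)) return(NULL)
  list(dim = dim(x) %||% length(x),
       hex = ifelse(is.na(as.vector(x)), "na", sprintf("%a", as.vector(x))))
}

dec_num <- function(o) {
  if (is.null(o)) return(NULL)
  v <- suppressWarnings(as.numeric(ifelse(o$hex == "na", NA, o$hex)))
  d <- as.integer(unlist(o$dim))
  if (length(d) > 1) array(v, dim = d) else v
}

enc_cplx <- function(x) {
  if (is.null(x)) return(NULL)
  list(dim = dim(x) %||% length(x),
       re = sprintf("%a", Re(as.vector(x))),
       im = sprintf("%a", Im(as.vector(x))))
}

dec_cplx <- function(o) {
  if (is.null(o)) return(NULL)
  v <- complex(real = as.numeric(o$re), imaginary = as.numeric(o$im))
  d <- as.integer(unlist(o$dim))
  if (length(d) > 1) array(v, dim = d) else v
}

MODEL_FORMAT_VERSION <- "1.0"

#' Serialize a fitted classifier to JSON
#'
#' Writes every model field to a structured text file; numeric arrays are
#' stored as hexadecimal floating-point literals so the round-trip through
#' [read_model()] is bit-exact (`read_model(write_model(m)) == m`
#' field-for-field, and round-tripped models give identical predictions).
#'
#' @param model A fitted `envsca_fit`.
#' @param path Output path (conventionally `.json`).
#' @return `model`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "envsca_fit"))
  payload <- list(
    format_version = MODEL_FORMAT_VERSION,
    method = model$method,
    state_space = model$state_space,
    ref_state = model$ref_state,
    categories = model$categories,
    t_ref = model$t_ref,
    bandwidth = model$bandwidth,
    kernel = model$kernel,
    weights = enc_num(model$weights),
    freqs = enc_num(model$freqs),
    k = model$k,
    group_labels = model$group_labels,
    n_per_group = model$n_per_group,
    Lambda = enc_num(model$Lambda),
    Gamma = enc_num(model$Gamma),
    kappa = enc_num(model$kappa),
    loo_rate = enc_num(model$loo_rate),
    select_prop = model$select_prop,
    selected_env = model$selected_env,
    selected_sca = model$selected_sca)
  if (!is.null(model$smb)) {
    payload$smb <- list(
      kind = model$smb$kind,
      theta = enc_num(model$smb$theta),
      group_labels = model$smb$group_labels,
      n_per_group = model$smb$n_per_group,
      freqs = enc_num(model$smb$freqs),
      f_bar = enc_cplx(model$smb$f_bar))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(model)
}

#' Read a serialized classifier
#'
#' @param path Path written by [write_model()].
#' @return The reconstructed `envsca_fit`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(cnd) {
                        abort(paste0("cannot parse model file '", path,
                                     "': ", conditionMessage(cnd)))
                      })
  if (!identical(payload$format_version, MODEL_FORMAT_VERSION)) {
    abort(paste0("model format version mismatch: file has '",
                 payload$format_version %||% "<missing>",
                 "', this package reads '", MODEL_FORMAT_VERSION, "'"))
  }
  smb <- NULL
  if (length(payload$smb)) {
    smb <- structure(
      list(group_labels = payload$smb$group_labels,
           n_per_group = as.integer(payload$smb$n_per_group),
           f_bar = dec_cplx(payload$smb$f_bar),
           freqs = dec_num(payload$smb$freqs),
           kind = payload$smb$kind,
           theta = dec_num(payload$smb$theta)),
      class = "smb_model")
  }
  new_envsca_fit(list(
    state_space = payload$state_space,
    ref_state = payload$ref_state,
    categories = payload$categories,
    t_ref = as.integer(payload$t_ref),
    bandwidth = as.integer(payload$bandwidth),
    kernel = payload$kernel,
    weights = dec_num(payload$weights),
    method = payload$method,
    group_labels = payload$group_labels,
    n_per_group = as.integer(payload$n_per_group),
    freqs = dec_num(payload$freqs),
    k = as.integer(payload$k),
    Lambda = dec_num(payload$Lambda),
    Gamma = dec_num(payload$Gamma),
    kappa = dec_num(payload$kappa) %||% NA_real_,
    loo_rate = dec_num(payload$loo_rate) %||% NA_real_,
    select_prop = payload$select_prop,
    selected_env = as.integer(payload$selected_env),
    selected_sca = as.integer(payload$selected_sca),
    smb = smb))
}
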