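#' Construct a regional PiB uptake table
#'
#' Per-VOI mean standardized uptake values with VOI volumes, plus the
#' cerebellar-cortex reference uptake. The amyloid protocol modelled here
#' uses 28 bilateral cerebral cortical VOIs; other counts are accepted with
#' a warning.
#'
#' @param voi data.frame with columns `voi_name`, `mean_suv`, `volume_ml`.
#' @param reference_suv mean standardized uptake of the cerebellar cortex.
#' @return An object of class `uptake_table`.
#' @export
uptake_table <- function(voi, reference_suv) {
  stopifnot(all(c("voi_name", "mean_suv", "volume_ml") %in% names(voi)))
  if (any(voi$volume_ml <= 0)) stop("VOI volumes must be positive")
  if (!is.finite(reference_suv) || reference_suv <= 0)
    stop("cerebellar reference uptake must be positive")
  if (nrow(voi) != 28)
    warning(sprintf("expected 28 cortical VOIs, got %d", nrow(voi)))
  structure(list(voi = voi[, c("voi_name", "mean_suv", "volume_ml")],
                 reference_suv = reference_suv),
            class = "uptake_table")
}

#' Global PiB retention ratio
#'
#' Volume-weighted average SUVR over the cortical VOIs: each VOI's SUVR is
#' its mean uptake divided by the cerebellar reference uptake, and the
#' global ratio is sum(volume_i * SUVR_i) / sum(volume_i). Invariant to
#' rescaling all uptakes by a common factor.
#'
#' @param table an [uptake_table()].
#' @return scalar global retention ratio.
#' @export
global_pib_ratio <- function(table) {
  suvr <- table$voi$mean_suv / table$reference_suv
  sum(table$voi$volume_ml * suvr) / sum(table$voi$volume_ml)
}

#' Assign the binary amyloid label
#'
#' A subject is PiB(+) iff the global retention ratio is strictly greater
#' than the threshold (default 1.5); a ratio exactly at the threshold is
#' PiB(-).
#'
#' @param ratio global retention ratio, finite and positive.
#' @param threshold positivity cut (default 1.5).
#' @return `"PiB_positive"` or `"PiB_negative"`.
#' @export
assign_pib_label <- function(ratio, threshold = 1.5) {
  if (!is.finite(ratio) || ratio <= 0) stop("retention ratio must be finite and positive")
  if (ratio > threshold) "PiB_positive" else "PiB_negative"
}

#' Read / write regional uptake tables as CSV
#'
#' Format: columns `voi_name`, `mean_suv`, `volume_ml`; the reference region
#' is the row with `voi_name == "cerebellar_cortex"` (its volume is unused).
#'
#' @param path CSV path.
#' @param table an [uptake_table()] (writer).
#' @return an [uptake_table()] (reader); `path` invisibly (writer).
#' @export
read_uptake_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ref <- df$voi_name == "cerebellar_cortex"
  if (sum(ref) != 1) stop("expected exactly one cerebellar_cortex reference row in ", path)
  uptake_table(df[!ref, , drop = FALSE], df$mean_suv[ref])
}

#' @rdname read_uptake_csv
#' @export
write_uptake_csv <- function(table, path) {
  df <- rbind(table$voi,
              data.frame(voi_name = "cerebellar_cortex",
                         mean_suv = table$reference_suv, volume_ml = 1))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
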