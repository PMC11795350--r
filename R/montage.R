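#' Standard 30-channel 10-20 electrode montage
#'
#' The fixed recording montage used throughout the pipeline: 30 scalp
#' electrodes of the international 10-20 system in their canonical order.
#' Every epoch array, connectivity matrix and graph in the package is
#' indexed by these labels, in this order.
#'
#' @return An object of class `montage`: a character vector of 30 unique
#'   channel labels with an `index` attribute mapping label to position.
#' @examples
#' m <- montage_1020()
#' length(m)        # 30
#' m[["Cz"]]        # label lookup by position name
#' @export
montage_1020 <- function() {
  labels <- c(
    "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FT7", "FC3", "FCz", "FC4", "FT8",
    "T7", "C3", "Cz", "C4", "T8",
    "TP7", "CP3", "CPz", "CP4", "TP8",
    "P7", "P3", "Pz", "P4", "P8",
    "O1", "Oz", "O2"
  )
  names(labels) <- labels
  structure(labels, index = stats::setNames(seq_along(labels), labels),
            class = "montage")
}

#' Position of channel labels within the montage
#'
#' @param labels character vector of channel labels.
#' @param montage a montage, by default [montage_1020()].
#' @return Integer positions (1-based). Errors on unknown labels.
#' @export
montage_index <- function(labels, montage = montage_1020()) {
  idx <- attr(montage, "index")[labels]
  if (anyNA(idx)) {
    stop("unknown channel label(s): ",
         paste(labels[is.na(idx)], collapse = ", "))
  }
  unname(idx)
}

#' @export
print.montage <- function(x, ...) {
  cat("10-20 montage:", length(x), "channels\n")
  cat(paste(strwrap(paste(x, collapse = " "), width = 70), collapse = "\n"),
      "\n")
  invisible(x)
}
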