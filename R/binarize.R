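#' Binarize ROI time series at the per-region time average
#'
#' Each region's continuous signal is thresholded at its own time mean: a
#' sample strictly above the mean becomes +1 (active), otherwise -1
#' (inactive). The tie rule (a sample exactly at the mean maps to -1) is
#' fixed so that results are reproducible; a constant region therefore
#' becomes all -1 and triggers a warning.
#'
#' @param ts Numeric matrix, rows = time points, columns = regions; an
#'   optional column-name header supplies region labels.
#' @return An object of class \code{binary_activity}: \code{values}
#'   (t_max x N matrix in \{-1, +1\}), \code{roi_names} and
#'   \code{thresholds} (the per-region means used).
#' @export
#' @examples
#' binarize(cbind(a = c(1, 3), b = c(0, 2)))$values
binarize <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 2L) stop("need at least 2 time points", call. = FALSE)
  if (!is.numeric(ts) || anyNA(ts) || !all(is.finite(ts))) {
    stop("time series must be numeric with no missing or non-finite values",
         call. = FALSE)
  }
  check_n_rois(ncol(ts))
  roi_names <- colnames(ts)
  if (is.null(roi_names)) roi_names <- paste0("ROI", seq_len(ncol(ts)))
  thresholds <- colMeans(ts)
  B <- matrix(-1L, nrow(ts), ncol(ts), dimnames = list(NULL, roi_names))
  B[sweep(ts, 2L, thresholds, ">")] <- 1L
  constant <- apply(ts, 2L, function(x) all(x == x[1L]))
  if (any(constant)) {
    warning("constant region(s) mapped to all -1 by the tie rule: ",
            paste(roi_names[constant], collapse = ", "), call. = FALSE)
  }
  structure(list(values = B, roi_names = roi_names,
                 thresholds = stats::setNames(thresholds, roi_names)),
            class = "binary_activity")
}

#' @export
print.binary_activity <- function(x, ...) {
  cat("Binary activity matrix:", nrow(x$values), "time points x",
      ncol(x$values), "regions\n")
  frac <- colMeans(x$values > 0)
  cat("  active fraction per region:",
      paste(sprintf("%s %.2f", x$roi_names, frac), collapse = ", "), "\n")
  invisible(x)
}

#' Collapse a binary activity matrix to a state-index sequence
#'
#' Each time point's +-1 pattern across regions is mapped to its state
#' index (see [state_index()]), yielding the time-ordered sequence of
#' visited states.
#'
#' @param b A [binarize()] result or a t_max x N matrix in \{-1, +1\}.
#' @return Integer vector of class \code{state_sequence} with attribute
#'   \code{n_rois}.
#' @export
to_state_sequence <- function(b) {
  B <- activity_values(b)
  seq <- state_index(B)
  structure(seq, n_rois = ncol(B), class = "state_sequence")
}

# Accept either a binary_activity object or a bare +-1 matrix.
activity_values <- function(b) {
  B <- if (inherits(b, "binary_activity")) b$values else as.matrix(b)
  if (!all(B == 1L | B == -1L)) {
    stop("binary activity must contain only -1 and +1", call. = FALSE)
  }
  B
}

activity_roi_names <- function(b) {
  if (inherits(b, "binary_activity")) return(b$roi_names)
  colnames(as.matrix(b))
}
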