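#' Define an isobaric labeling channel design
#'
#' A channel design describes the multiplexing layout of an isobaric labeling
#' experiment: the ordered reporter channels, which channel serves as the
#' ratio denominator, and the theoretical (expected) ratio of every other
#' channel to the denominator. With `k` channels there are `n = k - 1`
#' predefined ratios; their order follows the channel order with the
#' denominator removed.
#'
#' @param labels Character vector of channel labels in reporter m/z order,
#'   e.g. `c("126", "127", "128", "129", "130", "131")` for TMT 6-plex.
#' @param denominator 1-based index of the denominator channel (default the
#'   first channel).
#' @param theoretical_ratios Numeric vector of length `length(labels) - 1`
#'   giving the expected ratio of each non-denominator channel to the
#'   denominator, in channel order. Defaults to all 1 (equimolar design).
#' @return An object of class `channel_design` with elements `labels`,
#'   `denominator`, `theoretical_ratios` and `n_ratios`.
#' @examples
#' channel_design(c("126", "127", "128"))
#' channel_design(paste0("ch", 1:10), denominator = 10,
#'                theoretical_ratios = c(1, 1, 1, 0.5, 0.5, 0.5, 2, 2, 2))
#' @export
channel_design <- function(labels, denominator = 1L,
                           theoretical_ratios = NULL) {
  labels <- as.character(labels)
  if (length(labels) < 2L) stop("a channel design needs at least 2 channels")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  denominator <- as.integer(denominator)
  if (denominator < 1L || denominator > length(labels))
    stop("denominator index out of range")
  n <- length(labels) - 1L
  if (is.null(theoretical_ratios)) theoretical_ratios <- rep(1, n)
  if (length(theoretical_ratios) != n)
    stop("theoretical_ratios must have length ", n,
         " (channels minus the denominator)")
  if (any(!is.finite(theoretical_ratios)) || any(theoretical_ratios <= 0))
    stop("theoretical_ratios must be finite and positive")
  structure(
    list(labels = labels, denominator = denominator,
         theoretical_ratios = as.numeric(theoretical_ratios), n_ratios = n),
    class = "channel_design"
  )
}

#' @export
print.channel_design <- function(x, ...) {
  cat("Channel design:", length(x$labels), "channels (",
      paste(x$labels, collapse = ", "), ")\n")
  cat("  denominator:", x$labels[x$denominator], "\n")
  cat("  theoretical ratios:",
      paste(format(x$theoretical_ratios), collapse = ", "), "\n")
  invisible(x)
}

# Column names holding reporter intensities in a PSM table.
reporter_cols <- function(design) paste0("reporter_", design$labels)

# Labels of the numerator channels, in ratio order.
numerator_labels <- function(design) design$labels[-design$denominator]
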