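# Total Flag Sum (TFS) encoding and the early/mid/late temporal taxonomy.
#
# Each array of the three-array (or six-array) design contributes a binary
# flag (1, 2, 4; extended 8, 16, 32) when the gene meets the combined
# significance threshold on that array, plus a decimal digit recording the
# direction of regulation (1 = up, 2 = down, 0 = no call). The canonical
# code is the string "<binary sum>.<digits>". Codes are handled as strings
# throughout: decimal flag sums such as 0.1 + 0.01 are not exactly
# representable in binary floating point.

#' Subgroup labels of the temporal response taxonomy
#'
#' The twelve named early/mid/late subgroups, plus `"mixed/unclassified"`
#' for patterns with a sign reversal across called time points, plus
#' `"null"` for genes with no call. Together these partition all 27 ternary
#' three-array call patterns.
#'
#' @return Character vector of the 14 labels, in canonical order.
#' @export
subgroup_labels <- function() {
  c("early transient up", "early sustained up", "early persistent up",
    "early transient down", "early sustained down", "early persistent down",
    "mid transient up", "mid sustained up",
    "mid transient down", "mid sustained down",
    "late up", "late down",
    "mixed/unclassified", "null")
}

#' Temporal response archetypes
#'
#' The 14 single-direction call patterns of the three-array taxonomy (the
#' rows of the early/mid/late classification; "early transient" has two
#' patterns per direction, with and without a recurrence at 24 h), plus the
#' `"null"` archetype. Used by the simulator to plant ground-truth
#' responders and by the classifier tests.
#'
#' @return A data.frame with columns `archetype`, `call_3h`, `call_8h`,
#'   `call_24h` (values `"up"`/`"none"`/`"down"`) and `subgroup` (the label
#'   the classifier must assign).
#' @export
tfs_archetypes <- function() {
  u <- "up"; d <- "down"; n <- "none"
  out <- data.frame(
    archetype = c(
      "early_transient_up", "early_transient_up_24h",
      "early_sustained_up", "early_persistent_up",
      "early_transient_down", "early_transient_down_24h",
      "early_sustained_down", "early_persistent_down",
      "mid_transient_up", "mid_sustained_up",
      "mid_transient_down", "mid_sustained_down",
      "late_up", "late_down", "null"),
    call_3h  = c(u, u, u, u, d, d, d, d, n, n, n, n, n, n, n),
    call_8h  = c(n, n, u, u, n, n, d, d, u, u, d, d, n, n, n),
    call_24h = c(n, u, n, u, n, d, n, d, n, u, n, d, u, d, n),
    stringsAsFactors = FALSE
  )
  out$subgroup <- vapply(seq_len(nrow(out)), function(i)
    classify_subgroup(c(out$call_3h[i], out$call_8h[i], out$call_24h[i])),
    character(1))
  out
}

#' Encode a call pattern as a canonical Total Flag Sum code
#'
#' Arrays meeting the combined threshold contribute binary flags 1, 2, 4
#' (three-array design) or 1, 2, 4, 8, 16, 32 (six-array design); the
#' decimal digits record direction per array (1 = up, 2 = down, 0 = none).
#'
#' @param calls Character vector of `"up"`/`"none"`/`"down"`, one per array,
#'   in array order (3 h, 8 h, 24 h; six-array designs append the second
#'   concentration's arrays).
#' @param n_arrays Expected design size, 3 or 6.
#' @return Canonical code string, e.g. `"3.110"` for (up, up, none).
#' @seealso [decode_tfs()] for the inverse.
#' @examples
#' encode_tfs(c("up", "up", "none"))    # "3.110"
#' encode_tfs(c("down", "down", "none")) # "3.220"
#' @export
encode_tfs <- function(calls, n_arrays = length(calls)) {
  if (!n_arrays %in% c(3L, 6L))
    stop("TFS designs have 3 or 6 arrays, got ", n_arrays)
  if (!.is_call_vector(calls, n_arrays))
    stop("'calls' must be ", n_arrays, " values in {up, none, down}")
  flagged <- calls != "none"
  b <- sum(2L^(which(flagged) - 1L))
  digits <- c(up = "1", none = "0", down = "2")[calls]
  paste0(b, ".", paste(digits, collapse = ""))
}

#' Decode a Total Flag Sum code back to its call pattern
#'
#' @param code Canonical TFS code string (see [encode_tfs()]).
#' @return Character vector of calls, length 3 or 6.
#' @details Codes whose binary part contradicts the digit pattern (for
#'   example `"3.101"`: binary 3 requires nonzero digits at positions 1 and
#'   2 only) raise an integrity error.
#' @export
decode_tfs <- function(code) {
  if (!is.character(code) || length(code) != 1L ||
      !grepl("^[0-9]+\\.[012]+$", code))
    stop("malformed TFS code: ", deparse(code))
  parts <- strsplit(code, ".", fixed = TRUE)[[1]]
  b <- as.integer(parts[1])
  digits <- strsplit(parts[2], "")[[1]]
  n <- length(digits)
  if (!n %in% c(3L, 6L))
    stop("TFS code must carry 3 or 6 direction digits: ", code)
  calls <- c("0" = "none", "1" = "up", "2" = "down")[digits]
  names(calls) <- NULL
  b_expected <- sum(2L^(which(calls != "none") - 1L))
  if (b != b_expected)
    stop("inconsistent TFS code ", code, ": binary sum ", b,
         " does not match digit pattern (expected ", b_expected, ")")
  calls
}

#' Classify a three-array call pattern into its temporal subgroup
#'
#' Early = first call at 3 h, mid = first call at 8 h, late = call only at
#' 24 h. Among early responders, transient = no call at 8 h (a
#' same-direction recurrence at 24 h stays transient), sustained =
#' same-direction call at 8 h but none at 24 h, persistent = same direction
#' at all three time points; mid transient/sustained analogously. Patterns
#' with a sign reversal across called time points are
#' `"mixed/unclassified"`; the all-none pattern is `"null"`.
#'
#' @param calls Character vector of 3 calls ordered (3 h, 8 h, 24 h).
#' @return One label from [subgroup_labels()].
#' @examples
#' classify_subgroup(c("up", "none", "none"))   # early transient up
#' classify_subgroup(c("none", "up", "up"))     # mid sustained up
#' classify_subgroup(c("none", "none", "down")) # late down
#' @export
classify_subgroup <- function(calls) {
  if (!.is_call_vector(calls, 3L))
    stop("'calls' must be 3 values in {up, none, down}")
  called <- calls[calls != "none"]
  if (length(called) == 0L) return("null")
  if (length(unique(called)) > 1L) return("mixed/unclassified")
  dir <- called[1]
  first <- which(calls != "none")[1]
  if (first == 1L) {
    timing <- if (calls[2] == "none") "transient"
              else if (calls[3] == "none") "sustained"
              else "persistent"
    return(paste("early", timing, dir))
  }
  if (first == 2L) {
    timing <- if (calls[3] == "none") "transient" else "sustained"
    return(paste("mid", timing, dir))
  }
  paste("late", dir)
}

#' Six-array TFS code and common-response flags for two concentrations
#'
#' Concatenates the high-concentration calls (arrays 1-3) and the
#' low-concentration calls (arrays 4-6) into the extended six-flag TFS
#' code. A gene is a common early responder when it has a same-direction
#' call at the 3 h array of both concentrations; common mid and late
#' analogously for the 8 h and 24 h arrays.
#'
#' @param calls_high,calls_low Three-call vectors ordered (3 h, 8 h, 24 h)
#'   for the high (5 mM) and low (1 mM) concentration designs.
#' @return List with `tfs` (six-array code string), and logicals
#'   `common_early`, `common_mid`, `common_late`.
#' @export
classify_common_response <- function(calls_high, calls_low) {
  if (!.is_call_vector(calls_high, 3L) || !.is_call_vector(calls_low, 3L))
    stop("both call vectors must be 3 values in {up, none, down}")
  common <- vapply(1:3, function(i)
    calls_high[i] != "none" && calls_low[i] == calls_high[i], logical(1))
  list(tfs = encode_tfs(c(calls_high, calls_low), n_arrays = 6L),
       common_early = common[1], common_mid = common[2],
       common_late = common[3])
}

#' Tally genes per temporal subgroup
#'
#' @param call_matrix Character matrix or data.frame, genes x 3 arrays
#'   (3 h, 8 h, 24 h), cells in `"up"`/`"none"`/`"down"`. Row names are
#'   gene ids.
#' @return A data.frame with columns `subgroup` and `n`, one row per label
#'   of [subgroup_labels()] (zeros included), with attribute
#'   `n_responsive` = number of genes with at least one call.
#' @export
subgroup_census <- function(call_matrix) {
  m <- as.matrix(call_matrix)
  if (ncol(m) != 3L)
    stop("call matrix must have 3 columns (3 h, 8 h, 24 h)")
  labels <- apply(m, 1L, classify_subgroup)
  counts <- table(factor(labels, levels = subgroup_labels()))
  out <- data.frame(subgroup = names(counts), n = as.integer(counts),
                    stringsAsFactors = FALSE)
  attr(out, "n_responsive") <- sum(out$n[out$subgroup != "null"])
  out
}
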