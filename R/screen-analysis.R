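#' Mutation calls against a parent backbone
#'
#' A set of substitutions relative to the wild-type parent, in 1-based
#' parent numbering; N-terminal extension residues use labels -1, -2, ...
#' and carry no wild-type residue (`wt = NA`).
#'
#' @param position Integer position labels.
#' @param observed Observed residues (1-letter codes).
#' @param wt Wild-type residues (NA for extension calls).
#' @return A data frame of class `mutation_calls`, sorted by position.
#' @export
mutation_calls <- function(position = integer(0),
                           observed = character(0),
                           wt = rep(NA_character_, length(position))) {
  stopifnot(length(position) == length(observed),
            length(wt) == length(position))
  position <- as.integer(position)
  if (anyDuplicated(position)) stop("conflicting calls at one position")
  sub <- position > 0 & !is.na(wt)
  if (any(sub & wt == observed))
    stop("wt must differ from observed for substitutions")
  ord <- order(position)
  structure(data.frame(position = position[ord],
                       wt = as.character(wt)[ord],
                       observed = toupper(observed)[ord],
                       stringsAsFactors = FALSE),
            class = c("mutation_calls", "data.frame"))
}

#' @export
print.mutation_calls <- function(x, ...) {
  if (!nrow(x)) { cat("No mutations (wild type)\n"); return(invisible(x)) }
  lab <- ifelse(is.na(x$wt),
                sprintf("%s(%d)", x$observed, x$position),
                sprintf("%s%d%s", x$wt, x$position, x$observed))
  cat(paste(lab, collapse = ", "), "\n")
  invisible(x)
}

#' Call mutations of a peptide relative to its parent
#'
#' If the peptide has the parent's length, residues are compared position by
#' position. If it is longer by `e <= max_extension` residues, the first `e`
#' residues are N-terminal extension calls at labels `-e .. -1` and the
#' remainder is compared position-wise. Shorter peptides, or longer than the
#' allowed extension, raise an alignment error.
#'
#' @param peptide Observed peptide (1-letter codes).
#' @param parent Parent peptide.
#' @param max_extension Maximum allowed N-terminal extension (default 2).
#' @return A [mutation_calls()] data frame sorted by position.
#' @examples
#' call_mutations("HSQGTFTSDYSKYLDSRRAHDFVQWLLNT", glucagon_wt())
#' @export
call_mutations <- function(peptide, parent, max_extension = 2L) {
  peptide <- toupper(peptide); parent <- toupper(parent)
  e <- nchar(peptide) - nchar(parent)
  if (e < 0 || e > max_extension)
    stop("cannot align: peptide length ", nchar(peptide),
         " vs parent ", nchar(parent), " (max extension ", max_extension, ")")
  pep <- strsplit(peptide, "")[[1]]
  par <- strsplit(parent, "")[[1]]
  ext_pos <- if (e > 0) seq(-e, -1L) else integer(0)
  ext_res <- if (e > 0) pep[seq_len(e)] else character(0)
  core <- pep[(e + 1L):length(pep)]
  diff <- which(core != par)
  mutation_calls(position = c(ext_pos, diff),
                 observed = c(ext_res, core[diff]),
                 wt = c(rep(NA_character_, e), par[diff]))
}

#' Apply mutation calls to a parent peptide
#'
#' Inverse of [call_mutations()]: substitutes residues at positive positions
#' and prepends extension residues (labels must be contiguous from -1
#' downward). Round-trips: `call_mutations(apply_mutations(parent, calls),
#' parent)` reproduces `calls`.
#'
#' @param parent Parent peptide.
#' @param calls A [mutation_calls()] data frame.
#' @return The mutated peptide string.
#' @export
apply_mutations <- function(parent, calls) {
  parent <- toupper(parent)
  if (!nrow(calls)) return(parent)
  if (anyDuplicated(calls$position)) stop("conflicting calls at one position")
  par <- strsplit(parent, "")[[1]]
  sub <- calls[calls$position > 0, , drop = FALSE]
  if (any(sub$position > length(par)))
    stop("call position beyond parent length")
  if (any(!is.na(sub$wt) & sub$wt != par[sub$position]))
    stop("call wt residue does not match parent")
  par[sub$position] <- sub$observed
  ext <- calls[calls$position < 0, , drop = FALSE]
  if (nrow(ext)) {
    if (!setequal(ext$position, seq(-nrow(ext), -1L)))
      stop("extension labels must be contiguous from -1 downward")
    ext <- ext[order(ext$position), , drop = FALSE]
    par <- c(ext$observed, par)
  }
  paste(par, collapse = "")
}

#' Sub-library window layout
#'
#' Named sets of randomized position labels, one per sub-library. The
#' default mirrors a five-sub-library doped design on a 29-residue backbone:
#' four seven-residue windows (1-7, 8-14, 15-21, 22-28), each sharing the
#' C-terminal positions 27 and 28 (duplicates dropped), plus an extension
#' sub-library randomizing two N-terminal extension slots, positions 1-5,
#' and 27-28. Sub-libraries whose deduplicated position count differs from
#' `m` (the fourth window already contains 27 and 28) are kept but flagged
#' by [validate_layout()] with a warning, since the exact published window
#' boundaries are not recoverable.
#'
#' @param windows Named list of integer position vectors.
#' @return An object of class `window_layout`.
#' @export
window_layout <- function(windows) {
  stopifnot(is.list(windows), length(windows) >= 1L,
            !is.null(names(windows)))
  windows <- lapply(windows, function(w) sort(unique(as.integer(w))))
  structure(windows, class = "window_layout")
}

#' @rdname window_layout
#' @export
default_window_layout <- function() {
  window_layout(list(
    sub1 = c(1:7, 27, 28),
    sub2 = c(8:14, 27, 28),
    sub3 = c(15:21, 27, 28),
    sub4 = c(22:28, 27, 28),
    ext  = c(-2L, -1L, 1:5, 27, 28)))
}

#' @rdname window_layout
#' @param layout A `window_layout`.
#' @param m Expected number of randomized positions per sub-library.
#' @export
validate_layout <- function(layout, m = 9L) {
  stopifnot(inherits(layout, "window_layout"))
  bad <- names(layout)[lengths(layout) != m]
  if (length(bad))
    warning("sub-libraries with position count != ", m, ": ",
            paste(bad, collapse = ", "))
  invisible(layout)
}

#' Assign mutation calls to compatible sub-libraries
#'
#' Returns the names of every sub-library whose randomized position set
#' contains all of the clone's substitution positions; extension calls are
#' compatible only with sub-libraries that include the extension slots. An
#' empty result means the clone is inconsistent with the declared layout
#' (flagged, never reassigned).
#'
#' @param calls A [mutation_calls()] data frame.
#' @param layout A [window_layout()] (default [default_window_layout()]).
#' @return Character vector of compatible sub-library names (possibly
#'   empty).
#' @export
assign_sublibrary <- function(calls, layout = default_window_layout()) {
  stopifnot(inherits(layout, "window_layout"))
  pos <- calls$position
  names(layout)[vapply(layout, function(w) all(pos %in% w), logical(1))]
}

#' Positivity calls and hit summaries for screen readouts
#'
#' `positivity_call()` thresholds per-clone signals (positivity = signal
#' strictly above the threshold, which the screen defines arbitrarily).
#' `hit_summary()` tabulates two-receptor positivity into co-positive,
#' single-positive and negative counts, with fractions formatted
#' `"n/N (p%)"` (percent to the nearest integer).
#'
#' @param signals Numeric vector of readouts.
#' @param threshold Positivity threshold (finite).
#' @return `positivity_call()`: logical vector.
#' @export
positivity_call <- function(signals, threshold) {
  stopifnot(is.finite(threshold))
  signals > threshold
}

#' @rdname positivity_call
#' @param pos_a,pos_b Logical positivity on receptors A and B.
#' @export
hit_summary <- function(pos_a, pos_b) {
  stopifnot(length(pos_a) == length(pos_b))
  n <- length(pos_a)
  counts <- c(co_positive = sum(pos_a & pos_b),
              single_positive = sum(xor(pos_a, pos_b)),
              negative = sum(!pos_a & !pos_b))
  fractions <- counts / n
  formatted <- sprintf("%d/%d (%.0f%%)", counts, n, 100 * fractions)
  names(formatted) <- names(counts)
  list(n = n, counts = counts, fractions = fractions, formatted = formatted)
}

#' Per-variant enrichment across selection rounds
#'
#' Frequencies of every variant in every pool (absent = 0; frequencies sum
#' to 1 per round) and round-over-round fold changes. A variant absent in
#' the previous round but present now has an undefined fold change, flagged
#' `"new"`; absent in both rounds is flagged `"absent"`.
#'
#' @param pools List of `pool_state` objects (>= 2), in round order.
#' @return A long data frame with columns `variant`, `round`, `count`,
#'   `freq`, `fold` (NA where undefined), `status`.
#' @export
enrichment_table <- function(pools) {
  stopifnot(length(pools) >= 2L,
            all(vapply(pools, inherits, logical(1), "pool_state")))
  sigs <- unique(unlist(lapply(pools, function(p) p$variants$sig)))
  rounds <- vapply(pools, function(p) p$round, integer(1))
  counts <- vapply(pools, function(p) {
    v <- p$variants
    out <- setNames(numeric(length(sigs)), sigs)
    out[v$sig] <- v$count
    out
  }, numeric(length(sigs)))
  counts <- matrix(counts, nrow = length(sigs),
                   dimnames = list(sigs, rounds))
  freq <- sweep(counts, 2, colSums(counts), "/")
  out <- do.call(rbind, lapply(seq_along(pools), function(j) {
    fold <- rep(NA_real_, length(sigs))
    status <- rep("", length(sigs))
    if (j > 1) {
      prev <- freq[, j - 1]; cur <- freq[, j]
      ok <- prev > 0
      fold[ok] <- cur[ok] / prev[ok]
      status[!ok & cur > 0] <- "new"
      status[!ok & cur == 0] <- "absent"
    }
    data.frame(variant = sigs, round = rounds[j], count = counts[, j],
               freq = freq[, j], fold = fold, status = status,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}
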