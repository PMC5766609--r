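#' Doped library design
#'
#' A doped ("soft randomized") library design: a parent peptide with a set of
#' randomized positions, each of which retains the wild-type residue with
#' probability `p_wt` and otherwise substitutes one of `n_alternatives`
#' allowed residues (by convention the 18 non-wt, non-Cys amino acids).
#'
#' Position labels are 1-based on the parent sequence; N-terminal extension
#' slots use negative labels (-1 for the residue immediately before position
#' 1, -2 before that), and must be contiguous from -1 downward.
#'
#' @param parent Parent peptide as a 1-letter-code string.
#' @param randomized_positions Integer vector of position labels (unique;
#'   non-extension labels within `[1, nchar(parent)]`).
#' @param p_wt Probability that a randomized position retains the wild-type
#'   residue (default 0.45).
#' @param n_alternatives Number of allowed non-wt residues per randomized
#'   position (default 18 = 20 amino acids - wt - Cys).
#' @param library_size Physical clone count of the library (default 6e7).
#' @param name Optional design name.
#'
#' @return An object of class `doped_design`.
#' @examples
#' d <- doped_design(glucagon_wt(), randomized_positions = c(1:7, 27, 28))
#' d
#' @export
doped_design <- function(parent, randomized_positions, p_wt = 0.45,
                         n_alternatives = 18L, library_size = 6e7,
                         name = NULL) {
  stopifnot(is.character(parent), length(parent) == 1L, nchar(parent) >= 1L)
  parent <- toupper(parent)
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", parent))
    stop("parent must contain only standard 1-letter amino acid codes")
  pos <- as.integer(randomized_positions)
  if (anyNA(pos) || anyDuplicated(pos))
    stop("randomized_positions must be unique integers")
  L <- nchar(parent)
  core <- pos[pos > 0L]
  ext <- pos[pos < 0L]
  if (any(pos == 0L) || any(core > L))
    stop("non-extension position labels must lie in [1, ", L, "]")
  if (length(ext) && !setequal(ext, seq(-1L, min(ext))))
    stop("extension slots must be contiguous from -1 downward")
  if (!is.numeric(p_wt) || length(p_wt) != 1L || p_wt < 0 || p_wt > 1)
    stop("p_wt must be a probability in [0, 1]")
  n_alternatives <- as.integer(n_alternatives)
  if (n_alternatives < 1L) stop("n_alternatives must be >= 1")
  if (!is.numeric(library_size) || library_size < 1)
    stop("library_size must be >= 1")
  structure(
    list(parent = parent,
         randomized_positions = sort(pos),
         p_wt = p_wt,
         n_alternatives = n_alternatives,
         library_size = as.numeric(library_size),
         name = name),
    class = "doped_design")
}

#' @export
print.doped_design <- function(x, ...) {
  m <- length(x$randomized_positions)
  cat("Doped library design", if (!is.null(x$name)) paste0("'", x$name, "'"),
      "\n")
  cat("  parent  :", x$parent, sprintf("(%d aa)\n", nchar(x$parent)))
  cat("  doped   :", m, "positions [",
      paste(x$randomized_positions, collapse = ", "), "]\n")
  cat(sprintf("  p_wt    : %.2f  (%d alternatives per position)\n",
              x$p_wt, x$n_alternatives))
  cat(sprintf("  clones  : %.3g\n", x$library_size))
  invisible(x)
}

## allowed substitutes at a randomized position: the first n_alternatives
## non-wt, non-Cys residues (all 18 of them for the standard design)
design_alternatives <- function(design, wt) {
  alts <- setdiff(AA20, c(wt, "C"))
  if (design$n_alternatives > length(alts))
    stop("n_alternatives = ", design$n_alternatives, " exceeds the ",
         length(alts), " available non-wt, non-Cys residues")
  alts[seq_len(design$n_alternatives)]
}

#' Number of randomized positions of a design
#' @param design A `doped_design`.
#' @return Integer count.
#' @export
n_randomized <- function(design) {
  stopifnot(inherits(design, "doped_design"))
  length(design$randomized_positions)
}

#' Cumulative complexity of a pool of sub-libraries
#'
#' Total physical clone count across designs, e.g. five sub-libraries of
#' 6e7 clones pooled into a 3e8-clone library mix.
#'
#' @param designs A list of `doped_design` objects.
#' @return Total clone count.
#' @export
pool_complexity <- function(designs) {
  if (inherits(designs, "doped_design")) designs <- list(designs)
  stopifnot(length(designs) >= 1L,
            all(vapply(designs, inherits, logical(1), "doped_design")))
  sum(vapply(designs, function(d) d$library_size, numeric(1)))
}

#' Wild-type glucagon sequence
#'
#' The 29-residue human glucagon backbone used as the parent of the doped
#' sub-libraries.
#'
#' @return A string of 1-letter codes.
#' @export
glucagon_wt <- function() "HSQGTFTSDYSKYLDSRRAQDFVQWLMNT"
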