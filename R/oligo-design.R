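#' Codon mixture at one randomized position
#'
#' A probability mixture of trimer-block codons synthesized at a single
#' position of a degenerate oligo. Weights must sum to 1, no codon may be a
#' stop, and all codons must translate to distinct residues (one codon per
#' amino acid, the trimer-block convention).
#'
#' @param position_label Position label matching the design (1-based peptide
#'   numbering; negative for N-terminal extension slots).
#' @param codons Character vector of DNA triplets.
#' @param weights Numeric weights summing to 1.
#' @return An object of class `codon_mixture`.
#' @export
codon_mixture <- function(position_label, codons, weights) {
  codons <- toupper(codons)
  stopifnot(length(codons) == length(weights), length(codons) >= 1L)
  if (!all(grepl("^[ACGT]{3}$", codons))) stop("codons must be ACGT triplets")
  if (abs(sum(weights) - 1) > 1e-9) stop("mixture weights must sum to 1")
  if (any(weights < 0)) stop("mixture weights must be nonnegative")
  aa <- codon_to_aa(codons)
  if (any(aa == "*")) stop("stop codons are not allowed in a mixture")
  if (anyDuplicated(aa))
    stop("codons within one mixture must translate to distinct residues")
  structure(list(position_label = as.integer(position_label),
                 codons = codons, weights = as.numeric(weights),
                 residues = aa),
            class = "codon_mixture")
}

#' @export
print.codon_mixture <- function(x, ...) {
  cat(sprintf("Codon mixture @ position %d: %s\n", x$position_label,
              paste(sprintf("%s(%s)=%.4f", x$codons, x$residues, x$weights),
                    collapse = " ")))
  invisible(x)
}

#' Build doped codon mixtures for a design
#'
#' For each randomized position, the wild-type codon carries weight `p_wt`
#' and each of the `n_alternatives` non-wt, non-Cys residues carries weight
#' `(1 - p_wt) / n_alternatives`. N-terminal extension slots (which have no
#' wild-type residue) receive an equal mixture over all non-Cys residues.
#'
#' @param design A [doped_design()].
#' @param codon_choice Optional codon assignment: a named list, one element
#'   per position label (name = label), each a named character vector mapping
#'   residue to codon. Defaults to the highest-usage human codon everywhere.
#' @return A list of [codon_mixture()] objects, one per randomized position,
#'   in position order.
#' @export
build_codon_mixtures <- function(design, codon_choice = NULL) {
  stopifnot(inherits(design, "doped_design"))
  lapply(design$randomized_positions, function(pos) {
    if (pos > 0) {
      wt <- substr(design$parent, pos, pos)
      if (wt == "C") stop("Cys at a randomized position is not supported")
      alts <- design_alternatives(design, wt)
      res <- c(wt, alts)
      w <- c(design$p_wt, rep((1 - design$p_wt) / length(alts), length(alts)))
      res <- res[w > 0]; w <- w[w > 0]
    } else {
      res <- setdiff(AA20, "C")
      w <- rep(1 / length(res), length(res))
    }
    codons <- codons_for(res, pos, codon_choice)
    codon_mixture(pos, codons, w)
  })
}

codons_for <- function(residues, pos, codon_choice) {
  map <- NULL
  if (!is.null(codon_choice)) map <- codon_choice[[as.character(pos)]]
  vapply(residues, function(r) {
    cd <- if (!is.null(map) && !is.na(map[r])) map[[r]] else preferred_codon(r)
    if (is.null(cd) || is.na(cd)) stop("no codon assigned for residue ", r)
    cd
  }, character(1))
}

#' Degenerate oligo specification
#'
#' Fixed 5' and 3' flanks around a body of fixed codons and
#' [codon_mixture()] positions, modelling one synthesized library oligo.
#'
#' @param name Oligo name.
#' @param five_prime_flank,three_prime_flank Fixed DNA (ACGT; may be `""`).
#' @param body List whose elements are either fixed codon strings or
#'   `codon_mixture` objects.
#' @return An object of class `oligo_spec`.
#' @export
oligo_spec <- function(name, five_prime_flank = "", body = list(),
                       three_prime_flank = "") {
  five_prime_flank <- toupper(five_prime_flank)
  three_prime_flank <- toupper(three_prime_flank)
  for (f in c(five_prime_flank, three_prime_flank))
    if (nchar(f) && !grepl("^[ACGT]+$", f)) stop("flanks must be ACGT only")
  for (el in body) {
    if (inherits(el, "codon_mixture")) next
    if (is.character(el) && length(el) == 1L && grepl("^[ACGT]+$", toupper(el)))
      next
    stop("body elements must be fixed ACGT strings or codon_mixture objects")
  }
  structure(list(name = name, five_prime_flank = five_prime_flank,
                 body = body, three_prime_flank = three_prime_flank),
            class = "oligo_spec")
}

#' @export
print.oligo_spec <- function(x, ...) {
  nvar <- sum(vapply(x$body, inherits, logical(1), "codon_mixture"))
  cat(sprintf("Oligo spec '%s': 5'[%s] + %d body elements (%d variable) + 3'[%s]\n",
              x$name, x$five_prime_flank, length(x$body), nvar,
              x$three_prime_flank))
  invisible(x)
}

#' Build the coding-region oligo spec of a doped design
#'
#' Lays out the design's peptide-coding region codon by codon: randomized
#' positions become doped codon mixtures, all other positions fixed codons
#' for the wild-type residue (extension slots, having no wild-type, are
#' always mixtures).
#'
#' @inheritParams build_codon_mixtures
#' @param five_prime_flank,three_prime_flank Fixed DNA flanking the coding
#'   region (inside the cloning sites; default empty).
#' @return An [oligo_spec()].
#' @export
design_oligo_spec <- function(design, codon_choice = NULL,
                              five_prime_flank = "", three_prime_flank = "") {
  stopifnot(inherits(design, "doped_design"))
  mixtures <- build_codon_mixtures(design, codon_choice)
  names(mixtures) <- as.character(design$randomized_positions)
  ext <- design$randomized_positions[design$randomized_positions < 0]
  labels <- c(sort(ext), seq_len(nchar(design$parent)))
  body <- lapply(labels, function(pos) {
    key <- as.character(pos)
    if (key %in% names(mixtures)) return(mixtures[[key]])
    wt <- substr(design$parent, pos, pos)
    codons_for(wt, pos, codon_choice)[[1]]
  })
  oligo_spec(name = if (is.null(design$name)) "design" else design$name,
             five_prime_flank = five_prime_flank, body = body,
             three_prime_flank = three_prime_flank)
}

#' Restriction site
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence (ACGT).
#' @return An object of class `restriction_site`.
#' @export
restriction_site <- function(name, recognition) {
  recognition <- toupper(recognition)
  if (!nchar(recognition) || !grepl("^[ACGT]+$", recognition))
    stop("recognition sequence must be nonempty ACGT")
  structure(list(name = name, recognition = recognition),
            class = "restriction_site")
}

#' Default cloning enzymes: NcoI (CCATGG) and NotI (GCGGCCGC)
#' @return A named list of [restriction_site()] objects.
#' @export
cloning_sites <- function() {
  list(NcoI = restriction_site("NcoI", "CCATGG"),
       NotI = restriction_site("NotI", "GCGGCCGC"))
}

## ---- exact site probability by finite automaton ----
##
## Aho-Corasick-style automaton over the non-matching prefix states of the
## recognition sequences, with one absorbing "hit" state. The probability
## distribution over states is pushed through the oligo left to right; fixed
## bases are deterministic transitions, mixture codons weighted 3-step
## transitions. Exact and linear in oligo length.

site_automaton <- function(sites, both_strands = FALSE) {
  pats <- vapply(sites, function(s) s$recognition, character(1))
  if (both_strands) pats <- unique(c(pats, revcomp_chr(pats)))
  prefixes <- unique(unlist(lapply(pats, function(p)
    vapply(0:(nchar(p) - 1L), function(i) substr(p, 1, i), character(1)))))
  ## order by length so state 1 is the empty prefix
  prefixes <- prefixes[order(nchar(prefixes))]
  S <- length(prefixes)
  sink <- S + 1L
  letters4 <- c("A", "C", "G", "T")
  trans <- lapply(letters4, function(ch) {
    M <- matrix(0, sink, sink)
    M[sink, sink] <- 1
    for (i in seq_len(S)) {
      t <- paste0(prefixes[i], ch)
      hit <- any(vapply(pats, function(p)
        nchar(t) >= nchar(p) &&
          substr(t, nchar(t) - nchar(p) + 1L, nchar(t)) == p, logical(1)))
      if (hit) { M[sink, i] <- 1; next }
      ## longest suffix of t that is a tracked prefix
      j <- 1L
      for (l in seq(min(nchar(t), max(nchar(prefixes))), 1L)) {
        suf <- substr(t, nchar(t) - l + 1L, nchar(t))
        w <- match(suf, prefixes)
        if (!is.na(w)) { j <- w; break }
      }
      M[j, i] <- 1
    }
    M
  })
  names(trans) <- letters4
  codon_mat <- new.env(parent = emptyenv())
  structure(list(trans = trans, n_states = sink, sink = sink,
                 codon_mat = codon_mat),
            class = "site_automaton")
}

aut_codon_matrix <- function(aut, codon) {
  m <- aut$codon_mat[[codon]]
  if (is.null(m)) {
    ch <- strsplit(codon, "")[[1]]
    m <- aut$trans[[ch[3]]] %*% aut$trans[[ch[2]]] %*% aut$trans[[ch[1]]]
    assign(codon, m, envir = aut$codon_mat)
  }
  m
}

aut_push_fixed <- function(aut, p, dna) {
  if (!nchar(dna)) return(p)
  for (ch in strsplit(dna, "")[[1]]) p <- aut$trans[[ch]] %*% p
  p
}

#' Exact probability that a library oligo contains a restriction site
#'
#' Computes, by a finite-automaton (transfer-matrix) pass over the
#' position-wise codon mixture distribution, the exact probability that a
#' random library member contains at least one occurrence of at least one of
#' the recognition sequences. Scanning is on the coding strand by default
#' (sufficient for palindromic sites such as NcoI and NotI);
#' `both_strands = TRUE` adds the reverse complements of the recognition
#' sequences for non-palindromic enzymes.
#'
#' @param spec An [oligo_spec()].
#' @param sites List of [restriction_site()] objects (default NcoI + NotI).
#' @param both_strands Scan both strands? Default `FALSE`.
#' @param automaton Optional prebuilt automaton (internal reuse).
#' @return Probability in `[0, 1]`.
#' @export
site_probability <- function(spec, sites = cloning_sites(),
                             both_strands = FALSE, automaton = NULL) {
  stopifnot(inherits(spec, "oligo_spec"), length(sites) >= 1L)
  aut <- if (is.null(automaton)) site_automaton(sites, both_strands) else automaton
  p <- numeric(aut$n_states); p[1] <- 1
  p <- aut_push_fixed(aut, p, spec$five_prime_flank)
  for (el in spec$body) {
    if (inherits(el, "codon_mixture")) {
      q <- numeric(aut$n_states)
      for (i in seq_along(el$codons))
        q <- q + el$weights[i] * (aut_codon_matrix(aut, el$codons[i]) %*% p)
      p <- q
    } else {
      p <- aut_push_fixed(aut, p, toupper(el))
    }
  }
  p <- aut_push_fixed(aut, p, spec$three_prime_flank)
  as.numeric(p[aut$sink])
}

## ---- codon optimization ----

#' Optimize codon choices against unwanted restriction sites
#'
#' Deterministic coordinate descent over codon coordinates: for every peptide
#' position of the design's oligo (fixed wild-type codons and every residue
#' of every doped mixture), each synonymous candidate codon is tried in turn
#' and kept if it strictly lowers the exact [site_probability()]; sweeps
#' repeat until no coordinate improves. Ties break lexicographically on codon
#' order, so the result is deterministic given the input ordering.
#'
#' @inheritParams design_oligo_spec
#' @param sites Restriction sites to avoid (default NcoI + NotI).
#' @param candidates Candidate codons per residue: named list mapping residue
#'   to a character vector of codons. Defaults to all synonymous codons.
#' @param threshold Feasibility bound on the achieved probability (default
#'   0.0013); if the optimum is not below it, the result is flagged
#'   infeasible (reported, not raised).
#' @param max_sweeps Safety cap on descent sweeps.
#' @param both_strands Passed to [site_probability()].
#' @return A list with `codon_choice` (per-position residue-to-codon maps),
#'   `probability` (achieved site probability), `spec` (optimized
#'   [oligo_spec()]), `feasible`, and `sweeps`.
#' @export
optimize_codons <- function(design, sites = cloning_sites(),
                            candidates = NULL,
                            five_prime_flank = "", three_prime_flank = "",
                            threshold = 0.0013, max_sweeps = 10L,
                            both_strands = FALSE) {
  stopifnot(inherits(design, "doped_design"))
  if (is.null(candidates)) {
    candidates <- lapply(setNames(AA20, AA20), synonymous_codons)
  }
  for (r in AA20)
    if (is.null(candidates[[r]]) || !length(candidates[[r]]))
      stop("no candidate codons for residue ", r)
  aut <- site_automaton(sites, both_strands)
  ext <- design$randomized_positions[design$randomized_positions < 0]
  labels <- c(sort(ext), seq_len(nchar(design$parent)))
  ## current assignment: per position, named residue -> codon map
  residues_at <- lapply(labels, function(pos) {
    if (pos %in% design$randomized_positions) {
      if (pos > 0) {
        wt <- substr(design$parent, pos, pos)
        c(wt, design_alternatives(design, wt))
      } else setdiff(AA20, "C")
    } else substr(design$parent, pos, pos)
  })
  choice <- lapply(residues_at, function(res)
    setNames(vapply(res, function(r) candidates[[r]][1], character(1)), res))
  names(choice) <- as.character(labels)
  build <- function(ch) design_oligo_spec(design, codon_choice = ch,
                                          five_prime_flank = five_prime_flank,
                                          three_prime_flank = three_prime_flank)
  best <- site_probability(build(choice), sites, automaton = aut)
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    improved <- FALSE
    for (li in seq_along(labels)) {
      key <- as.character(labels[li])
      for (r in names(choice[[key]])) {
        for (cd in candidates[[r]]) {
          if (cd == choice[[key]][[r]]) next
          trial <- choice
          trial[[key]][[r]] <- cd
          pr <- site_probability(build(trial), sites, automaton = aut)
          if (pr < best - 1e-15) {
            choice <- trial; best <- pr; improved <- TRUE
          }
        }
      }
    }
    if (!improved || sweeps >= max_sweeps || best == 0) break
  }
  list(codon_choice = choice, probability = best, spec = build(choice),
       feasible = best < threshold, sweeps = sweeps)
}

## ---- duplex assembly and digestion ----

#' Assemble a primer-extension duplex from two oligos
#'
#' Locates the longest 3'-terminal region of the forward oligo that is
#' complementary to the 3'-terminal region of the reverse oligo (both given
#' 5' to 3'), then models full primer extension: the duplex top strand is the
#' forward oligo extended by the reverse complement of the reverse oligo's
#' non-overlapping 5' portion.
#'
#' @param forward,reverse Oligos, 5' to 3', ACGT.
#' @param min_overlap Minimum acceptable complementary overlap (default 6).
#' @return A list with `duplex` (top strand of the extended product),
#'   `overlap` (length of the annealed region), and `length`.
#' @export
assemble_duplex <- function(forward, reverse, min_overlap = 6L) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  stopifnot(grepl("^[ACGT]+$", forward), grepl("^[ACGT]+$", reverse))
  nf <- nchar(forward); nr <- nchar(reverse)
  overlap <- 0L
  for (l in seq(min(nf, nr), 1L)) {
    fs <- substr(forward, nf - l + 1L, nf)
    rs <- substr(reverse, nr - l + 1L, nr)
    if (fs == revcomp_chr(rs)) { overlap <- l; break }
  }
  if (overlap < min_overlap)
    stop("no complementary 3' overlap of at least ", min_overlap, " nt")
  duplex <- paste0(forward, revcomp_chr(substr(reverse, 1L, nr - overlap)))
  list(duplex = duplex, overlap = overlap, length = nchar(duplex))
}

#' Locate restriction sites and check clonability
#'
#' Finds all occurrences (0-based, top strand) of each enzyme's recognition
#' sequence in a duplex. The duplex is "clonable" when every listed enzyme
#' cuts exactly once and the cuts appear in the listed order (for the default
#' NcoI + NotI pair: one NcoI site 5' of one NotI site).
#'
#' @param duplex Top-strand DNA (ACGT).
#' @param enzymes List of [restriction_site()] objects (default NcoI + NotI).
#' @return A list with `positions` (named list of 0-based integer vectors)
#'   and `clonable` (logical).
#' @export
digest_check <- function(duplex, enzymes = cloning_sites()) {
  duplex <- toupper(duplex)
  stopifnot(grepl("^[ACGT]+$", duplex))
  positions <- lapply(enzymes, function(e) {
    ## zero-width lookahead finds overlapping occurrences too
    hits <- gregexpr(paste0("(?=", e$recognition, ")"), duplex,
                     perl = TRUE)[[1]]
    if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
  })
  names(positions) <- vapply(enzymes, function(e) e$name, character(1))
  ones <- all(lengths(positions) == 1L)
  ordered <- ones && !is.unsorted(unlist(positions), strictly = TRUE)
  list(positions = positions, clonable = ones && ordered)
}
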