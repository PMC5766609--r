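MODIFIER_VOCAB <- c("\u03b3E\u03b3EC16")

#' Peptide with stereochemistry and side-chain modifiers
#'
#' Residue-level peptide representation: each residue has a 1-letter code, a
#' chirality (`"L"` or `"D"`), and an optional side-chain modifier from a
#' registered vocabulary (default: `"γEγEC16"`, the
#' gamma-Glu-gamma-Glu-palmitoyl PK modifier). C-terminal amidation is a
#' flag, not part of the sequence.
#'
#' The string serialization writes D-residues as lowercase letters and
#' modifiers parenthesized after the residue, e.g. `"HsQGTFTSDK(γEγEC16)..."`.
#'
#' @param code Residue 1-letter codes (uppercase).
#' @param chirality `"L"` or `"D"` per residue.
#' @param modifier Side-chain modifier per residue (`""` if none).
#' @param c_amide C-terminal amide flag (default `TRUE`).
#' @param vocab Allowed modifier strings.
#' @return An object of class `peptide_seq`.
#' @export
peptide_seq <- function(code, chirality = rep("L", length(code)),
                        modifier = rep("", length(code)), c_amide = TRUE,
                        vocab = MODIFIER_VOCAB) {
  code <- toupper(code)
  stopifnot(all(code %in% AA20), all(chirality %in% c("L", "D")),
            length(chirality) == length(code),
            length(modifier) == length(code))
  bad <- modifier[nzchar(modifier) & !(modifier %in% vocab)]
  if (length(bad))
    stop("unregistered side-chain modifier(s): ", paste(bad, collapse = ", "))
  structure(list(code = code, chirality = chirality, modifier = modifier,
                 c_amide = isTRUE(c_amide)),
            class = "peptide_seq")
}

#' @rdname peptide_seq
#' @param x For `parse_peptide()`, the serialized string (lowercase =
#'   D-residue, `(modifier)` after a residue).
#' @export
parse_peptide <- function(x, c_amide = TRUE, vocab = MODIFIER_VOCAB) {
  if (inherits(x, "peptide_seq")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  toks <- regmatches(x, gregexpr("[A-Za-z](\\([^)]*\\))?", x))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(x))
    stop("cannot parse peptide string: ", x)
  letter <- substr(toks, 1, 1)
  modifier <- ifelse(nchar(toks) > 1,
                     substr(toks, 3, nchar(toks) - 1L), "")
  peptide_seq(code = toupper(letter),
              chirality = ifelse(letter %in% letters, "D", "L"),
              modifier = modifier, c_amide = c_amide, vocab = vocab)
}

#' @rdname peptide_seq
#' @param pep A `peptide_seq`.
#' @export
format_peptide <- function(pep) {
  stopifnot(inherits(pep, "peptide_seq"))
  letter <- ifelse(pep$chirality == "D", tolower(pep$code), pep$code)
  paste0(paste0(letter, ifelse(nzchar(pep$modifier),
                               paste0("(", pep$modifier, ")"), "")),
         collapse = "")
}

#' @export
print.peptide_seq <- function(x, ...) {
  cat(format_peptide(x),
      if (x$c_amide) "(C-terminal amide)" else "(free C-terminus)", "\n")
  invisible(x)
}

#' Classification parameters for two-receptor activity
#'
#' @param potent_30,potent_80 Potency sub-tier thresholds in nM, applied
#'   inclusively to printed means (defaults 0.030 and 0.080 nM).
#' @param balance Inclusive window on the GCGR/GLP1R EC50 ratio defining a
#'   balanced co-agonist (default `c(0.5, 1.5)`).
#' @param inactive EC50 bound (nM) above which a receptor counts as not
#'   meaningfully activated (default 20 nM).
#' @return An object of class `classification_params`.
#' @export
classification_params <- function(potent_30 = 0.030, potent_80 = 0.080,
                                  balance = c(0.5, 1.5), inactive = 20) {
  stopifnot(potent_30 > 0, potent_80 > 0, inactive > 0,
            length(balance) == 2L, balance[1] <= balance[2])
  structure(list(potent_30 = potent_30, potent_80 = potent_80,
                 balance = balance, inactive = inactive),
            class = "classification_params")
}

#' EC50 ratio of a two-receptor activity record
#'
#' GCGR EC50 divided by GLP1R EC50 (mean values). Undefined (NA) whenever
#' either side is censored (`"> bound"`); censored values are never imputed.
#'
#' @param ec50_gcgr,ec50_glp1r EC50 means in nM (for censored entries, the
#'   bound).
#' @param censored_gcgr,censored_glp1r Logical censor flags.
#' @return Numeric ratio(s), NA where undefined.
#' @export
ec50_ratio <- function(ec50_gcgr, ec50_glp1r,
                       censored_gcgr = FALSE, censored_glp1r = FALSE) {
  if (any(ec50_gcgr <= 0, na.rm = TRUE) || any(ec50_glp1r <= 0, na.rm = TRUE))
    stop("EC50 means must be positive")
  ifelse(censored_gcgr | censored_glp1r, NA_real_, ec50_gcgr / ec50_glp1r)
}

#' Classify a two-receptor activity record
#'
#' Tiers: `inactive` (neither receptor activated below the inactivity
#' bound), `single-agonist` (one receptor), or co-agonist, split into
#' `co-agonist-balanced` when the GCGR/GLP1R ratio falls inside the
#' (inclusive) balance window and `co-agonist-biased` otherwise, with the
#' bias direction recorded (`ratio < lower` means more potent on GCGR).
#' Censored EC50s exceed every finite threshold. A potency sub-tier records
#' whether both means pass 30 pM, 80 pM, or neither (inclusive).
#'
#' @inheritParams ec50_ratio
#' @param params A [classification_params()].
#' @return A data frame with columns `tier`, `direction`, `potency_tier`,
#'   `ratio` (one row per record).
#' @export
classify <- function(ec50_gcgr, ec50_glp1r,
                     censored_gcgr = FALSE, censored_glp1r = FALSE,
                     params = classification_params()) {
  n <- max(length(ec50_gcgr), length(ec50_glp1r))
  ec50_gcgr <- rep_len(ec50_gcgr, n); ec50_glp1r <- rep_len(ec50_glp1r, n)
  censored_gcgr <- rep_len(censored_gcgr, n)
  censored_glp1r <- rep_len(censored_glp1r, n)
  active_g <- !censored_gcgr & ec50_gcgr <= params$inactive
  active_l <- !censored_glp1r & ec50_glp1r <= params$inactive
  ratio <- ec50_ratio(ec50_gcgr, ec50_glp1r, censored_gcgr, censored_glp1r)
  pass <- function(th) !censored_gcgr & !censored_glp1r &
    ec50_gcgr <= th & ec50_glp1r <= th
  tier <- character(n); direction <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!active_g[i] && !active_l[i]) {
      tier[i] <- "inactive"
    } else if (xor(active_g[i], active_l[i])) {
      tier[i] <- "single-agonist"
      direction[i] <- if (active_g[i]) "GCGR" else "GLP1R"
    } else if (!is.na(ratio[i]) && ratio[i] >= params$balance[1] &&
               ratio[i] <= params$balance[2]) {
      tier[i] <- "co-agonist-balanced"
    } else {
      tier[i] <- "co-agonist-biased"
      direction[i] <- if (!is.na(ratio[i]) && ratio[i] < params$balance[1])
        "GCGR" else "GLP1R"
    }
  }
  potency_tier <- ifelse(pass(params$potent_30), "<=30pM",
                         ifelse(pass(params$potent_80), "<=80pM", "other"))
  data.frame(tier = tier, direction = direction,
             potency_tier = potency_tier, ratio = ratio,
             stringsAsFactors = FALSE)
}

#' Summarize a two-receptor activity table
#'
#' Deterministic counts over an activity table (as returned by
#' [read_activity_csv()]): tier counts, the number of peptides with both
#' printed means at or below the 80 pM and 30 pM thresholds, the number of
#' undefined (censored) ratios, and balanced-window counts in both ratio
#' directions (the window is symmetric conventions differ between reports).
#'
#' @param table Data frame with columns `ec50_gcgr`, `ec50_glp1r`,
#'   `censored_gcgr`, `censored_glp1r`.
#' @param params A [classification_params()].
#' @return A list of counts.
#' @export
summarize_activity <- function(table, params = classification_params()) {
  stopifnot(nrow(table) >= 1L)
  cls <- classify(table$ec50_gcgr, table$ec50_glp1r,
                  table$censored_gcgr, table$censored_glp1r, params)
  unc <- !table$censored_gcgr & !table$censored_glp1r
  both_le <- function(th) sum(unc & table$ec50_gcgr <= th &
                                table$ec50_glp1r <= th)
  ratio <- cls$ratio
  in_win <- function(r) !is.na(r) & r >= params$balance[1] &
    r <= params$balance[2]
  list(n = nrow(table),
       tiers = table(cls$tier),
       potent_80 = both_le(params$potent_80),
       potent_30 = both_le(params$potent_30),
       nd_ratio = sum(is.na(ratio)),
       balanced_gcgr_over_glp1r = sum(in_win(ratio)),
       balanced_glp1r_over_gcgr = sum(in_win(1 / ratio)),
       classification = cls)
}

#' DPP-IV liability of a peptide
#'
#' Dipeptidyl peptidase IV cleaves after residue 2 of a free N-terminus when
#' position 2 is an L-configured Ser, Ala or Pro. A D-residue at position 2
#' (or any other residue) removes the liability.
#'
#' @param peptide A [peptide_seq()] or serialized peptide string.
#' @return A list with `liable` (logical) and `site` (description or NA).
#' @export
dppiv_liability <- function(peptide) {
  pep <- parse_peptide(peptide)
  stopifnot(length(pep$code) >= 2L)
  liable <- pep$chirality[2] == "L" && pep$code[2] %in% c("S", "A", "P")
  list(liable = liable,
       site = if (liable)
         sprintf("%s1-%s2 (cleavage after residue 2)", pep$code[1],
                 pep$code[2]) else NA_character_)
}

#' Default peptide-engineering rule set
#'
#' The drug-likeness transformations applied to phage-derived leads:
#' position 2 to D-Ser (removing the DPP-IV site) and position 10 to Lys
#' carrying the `γEγEC16` PK-modifier (gamma-Glu-gamma-Glu-palmitoyl).
#'
#' @return A list of rules (each with `position`, `residue`, `chirality`,
#'   `modifier`).
#' @export
default_engineering_rules <- function() {
  list(list(position = 2L, residue = "S", chirality = "D", modifier = ""),
       list(position = 10L, residue = "K", chirality = "L",
            modifier = MODIFIER_VOCAB[1]))
}

#' Apply engineering rules to a peptide
#'
#' Each rule replaces the residue at one position with a given residue,
#' chirality and optional side-chain modifier. Length and all unmodified
#' residues are preserved; a rule targeting a position beyond the peptide is
#' an error.
#'
#' @param peptide A [peptide_seq()] or serialized string.
#' @param rules Rule list (default [default_engineering_rules()]).
#' @return The engineered [peptide_seq()].
#' @examples
#' lead <- "HSQGTFTSDYSKYLDSRRAHDFVQWLLNT"
#' format_peptide(apply_engineering(lead))
#' @export
apply_engineering <- function(peptide, rules = default_engineering_rules()) {
  pep <- parse_peptide(peptide)
  for (r in rules) {
    i <- as.integer(r$position)
    if (i < 1L || i > length(pep$code))
      stop("engineering rule targets absent position ", i)
    pep$code[i] <- toupper(r$residue)
    pep$chirality[i] <- if (is.null(r$chirality)) "L" else r$chirality
    pep$modifier[i] <- if (is.null(r$modifier)) "" else r$modifier
  }
  peptide_seq(pep$code, pep$chirality, pep$modifier, pep$c_amide)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Fits `response = bottom + (top - bottom) / (1 + (ec50/dose)^hill)` by
#' Levenberg-Marquardt least squares and returns the EC50 with an
#' approximate 95% confidence interval. Non-convergence (e.g. a flat
#' response) is flagged rather than raised.
#'
#' @param dose Doses (same units as the returned EC50; > 0).
#' @param response Responses at each dose.
#' @return An object of class `dose_response_fit` with elements `ec50`,
#'   `ci`, `coef`, `converged`, `fit`.
#' @export
fit_dose_response <- function(dose, response) {
  stopifnot(length(dose) == length(response), length(dose) >= 5L,
            all(dose > 0))
  start <- list(bottom = min(response), top = max(response),
                log_ec50 = stats::median(log(dose)), hill = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ bottom + (top - bottom) /
        (1 + exp(hill * (log_ec50 - log(dose)))),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(stats::coef(fit)[["log_ec50"]]) ||
      abs(stats::coef(fit)[["top"]] - stats::coef(fit)[["bottom"]]) <
      1e-8 * max(1, abs(stats::coef(fit)[["top"]]))) {
    return(structure(list(ec50 = NA_real_, ci = c(NA_real_, NA_real_),
                          coef = NULL, converged = FALSE, fit = fit),
                     class = "dose_response_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["log_ec50"]],
                 error = function(e) NA_real_)
  ec50 <- exp(cf[["log_ec50"]])
  ci <- if (is.finite(se))
    exp(cf[["log_ec50"]] + c(-1, 1) * 1.96 * se) else c(NA_real_, NA_real_)
  structure(list(ec50 = ec50, ci = ci, coef = cf, converged = TRUE,
                 fit = fit),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged) {
    cat("4PL dose-response fit: did not converge\n")
  } else {
    cat(sprintf("4PL dose-response fit: EC50 = %.4g [%.4g, %.4g]\n",
                x$ec50, x$ci[1], x$ci[2]))
  }
  invisible(x)
}

#' @method coef dose_response_fit
#' @export
coef.dose_response_fit <- function(object, ...) object$coef
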