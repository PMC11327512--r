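#' Chi-square test statistic for a contingency table
#'
#' Pearson chi-square for an r x c table of counts, optionally with the
#' Yates continuity correction (2 x 2 tables only). Group-comparison
#' convention for the cohort tables: the 2 x 2 sex table uses the
#' correction; wider comorbidity tables do not.
#'
#' @param counts non-negative integer matrix of counts.
#' @param continuity_correction apply the Yates correction (2 x 2 only).
#' @return list with `statistic`, `df` and `p_value`.
#' @export
chiSquareTable <- function(counts, continuity_correction = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column marginal; expected counts are undefined")
  if (continuity_correction && !all(dim(counts) == 2L))
    stop("continuity correction applies to 2 x 2 tables only")
  ct <- suppressWarnings(chisq.test(counts, correct = continuity_correction))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#' marginal-product expected agreement.
#'
#' @param ratings_a,ratings_b equal-length categorical vectors.
#' @return kappa in \[-1, 1\].
#' @export
cohenKappa <- function(ratings_a, ratings_b) {
  stopifnot(length(ratings_a) == length(ratings_b), length(ratings_a) > 0)
  levs <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  a <- factor(as.character(ratings_a), levels = levs)
  b <- factor(as.character(ratings_b), levels = levs)
  tab <- table(a, b) / length(a)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (pe >= 1) stop("chance agreement is 1; kappa undefined")
  (po - pe) / (1 - pe)
}

#' Participant-flow arithmetic
#'
#' Applies a ledger of per-stage exclusion deltas to the enrollment counts
#' of the two groups and reports the running totals, erroring if any
#' running count goes negative.
#'
#' @param enrollment length-2 integer vector `c(normal, aspiration)` at
#'   enrollment.
#' @param ledger data.frame with columns `stage`, `normal`, `aspiration`
#'   (deltas; exclusions are negative). May have zero rows.
#' @return data.frame with per-stage running counts (columns `stage`,
#'   `normal`, `aspiration`, `total`), starting at enrollment.
#' @export
participantFlow <- function(enrollment, ledger = data.frame()) {
  stopifnot(length(enrollment) == 2L, all(enrollment >= 0))
  out <- data.frame(stage = "enrollment", normal = enrollment[1L],
                    aspiration = enrollment[2L], stringsAsFactors = FALSE)
  if (nrow(ledger)) {
    stopifnot(all(c("stage", "normal", "aspiration") %in% names(ledger)))
    for (i in seq_len(nrow(ledger))) {
      nrm <- out$normal[nrow(out)] + ledger$normal[i]
      asp <- out$aspiration[nrow(out)] + ledger$aspiration[i]
      if (nrm < 0 || asp < 0)
        stop("running count goes negative at stage '", ledger$stage[i], "'")
      out <- rbind(out, data.frame(stage = ledger$stage[i], normal = nrm,
                                   aspiration = asp))
    }
  }
  out$total <- out$normal + out$aspiration
  out
}
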