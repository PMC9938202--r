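## Statistics layer: quartile phenotyping of drinking behaviour,
## Kruskal-Wallis group comparisons, and session-by-metric Spearman
## correlation matrices with Benjamini-Hochberg correction.

#' Final-window mean intake per animal
#'
#' @param behavior Intake data.frame (`animal_id`, `session`, `phase`,
#'   `intake_ml`) or a [BehaviorCohort-class].
#' @param finalWindow Number of last training sessions to average
#'   (default 3).
#' @return Named numeric of per-animal means.
#' @export
finalWindowMean <- function(behavior, finalWindow = 3) {
  if (is(behavior, "BehaviorCohort")) behavior <- intakeTable(behavior)
  tr <- behavior[behavior$phase != "baseline", , drop = FALSE]
  last <- sort(unique(tr$session), decreasing = TRUE)[seq_len(finalWindow)]
  sel <- tr[tr$session %in% last, , drop = FALSE]
  means <- tapply(sel$intake_ml, sel$animal_id, mean)
  setNames(as.numeric(means), names(means))
}

#' Quartile phenotyping of drinking behaviour
#'
#' Animals are ranked by their mean water intake over the last
#' `finalWindow` training sessions; the upper quartile (`floor(N/4)`
#' animals) are labelled high drinkers (HD, the compulsive phenotype), the
#' lower quartile low drinkers (LD), and the remainder intermediate. Ties
#' at a quartile boundary are broken by the mean over all earlier training
#' sessions, then by animal id, so the assignment is deterministic and
#' invariant to row order.
#'
#' @param behavior Intake data.frame or [BehaviorCohort-class].
#' @param finalWindow Sessions in the selection window (default 3).
#' @return data.frame with columns `animal_id`, `statistic` (final-window
#'   mean, mL) and `phenotype` (`"HD"`, `"LD"` or `"intermediate"`).
#' @export
phenotypeQuartiles <- function(behavior, finalWindow = 3) {
  if (is(behavior, "BehaviorCohort")) behavior <- intakeTable(behavior)
  stat <- finalWindowMean(behavior, finalWindow)
  n <- length(stat)
  if (n < 4) stop("quartile phenotyping needs at least 4 animals")
  tr <- behavior[behavior$phase != "baseline", , drop = FALSE]
  last <- sort(unique(tr$session), decreasing = TRUE)[seq_len(finalWindow)]
  early <- tr[!(tr$session %in% last), , drop = FALSE]
  earlyMean <- setNames(rep(0, n), names(stat))
  if (nrow(early)) {
    em <- tapply(early$intake_ml, early$animal_id, mean)
    earlyMean[names(em)] <- as.numeric(em)
  }
  ids <- names(stat)
  ord <- order(-stat, -earlyMean, ids)          # best drinker first
  k <- floor(n / 4)
  phen <- rep("intermediate", n)
  phen[ord[seq_len(k)]] <- "HD"
  phen[ord[n + 1 - seq_len(k)]] <- "LD"
  out <- data.frame(animal_id = ids, statistic = as.numeric(stat),
                    phenotype = phen)
  out[order(out$animal_id), , drop = FALSE]
}

#' Kruskal-Wallis comparison of animal-level values
#'
#' Rank-based k-group comparison on mid-ranks with tie correction; the
#' statistic H is referred to a chi-square distribution with k - 1 degrees
#' of freedom. Optional pairwise follow-ups are two-group Kruskal-Wallis
#' contrasts, unadjusted by default (set `adjustPairwise` for BH over the
#' contrasts).
#'
#' Degenerate input (all values identical across groups) yields H = 0 with
#' `degenerate = TRUE`; the tie-corrected statistic is defined as 0 there.
#'
#' @param groups Named list of numeric vectors, one per group (each
#'   non-empty).
#' @param pairwise Also run all two-group contrasts.
#' @param adjustPairwise Apply BH across the pairwise p-values.
#' @return List with `H`, `df`, `p.value`, `degenerate`, and (if requested)
#'   a `pairwise` data.frame of contrasts.
#' @examples
#' kruskalWallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))$H  # 3.857
#' @export
kruskalWallis <- function(groups, pairwise = FALSE, adjustPairwise = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 2)
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("every group must contain observations")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  if (length(unique(x)) == 1) {
    res <- list(H = 0, df = length(groups) - 1L, p.value = 1,
                degenerate = TRUE)
  } else {
    kw <- kruskal.test(x, g)
    res <- list(H = unname(kw$statistic), df = unname(kw$parameter),
                p.value = kw$p.value, degenerate = FALSE)
  }
  if (pairwise) {
    nm <- names(groups)
    if (is.null(nm)) nm <- paste0("g", seq_along(groups))
    cmb <- utils::combn(seq_along(groups), 2)
    pw <- data.frame(
      group1 = nm[cmb[1, ]], group2 = nm[cmb[2, ]],
      H = NA_real_, p.value = NA_real_)
    for (j in seq_len(ncol(cmb))) {
      sub <- kruskalWallis(groups[cmb[, j]])
      pw$H[j] <- sub$H; pw$p.value[j] <- sub$p.value
    }
    if (adjustPairwise) pw$p.adj <- p.adjust(pw$p.value, method = "BH")
    res$pairwise <- pw
  }
  res
}

#' Session-by-metric Spearman correlation matrix with BH correction
#'
#' For every (session, metric) cell, computes the Spearman correlation
#' (mid-ranks, average ranks for ties) between per-animal water intake in
#' that session and the animal-level metric, with a two-sided p-value.
#' Benjamini-Hochberg step-up correction is applied over all cells of the
#' matrix as a single family. Cells where either vector is constant are
#' undefined and reported as missing.
#'
#' @param behavior Intake data.frame or [BehaviorCohort-class]; rows of the
#'   matrix are its sessions (baseline sessions labelled `base<k>`,
#'   training sessions `s<k>`).
#' @param metrics data.frame of animal-level metrics with an `animal_id`
#'   column; remaining numeric columns become matrix columns.
#' @param alpha Significance level for the flag matrix (default 0.05).
#' @return A [CorrelationMatrix-class].
#' @export
spearmanBH <- function(behavior, metrics, alpha = 0.05) {
  if (is(behavior, "BehaviorCohort")) behavior <- intakeTable(behavior)
  stopifnot("animal_id" %in% names(metrics))
  mcols <- setdiff(names(metrics), "animal_id")
  mcols <- mcols[vapply(metrics[mcols], is.numeric, logical(1))]
  if (!length(mcols)) stop("metrics must contain numeric columns")
  sess <- unique(behavior[, c("session", "phase")])
  sess <- sess[order(sess$session), , drop = FALSE]
  rowNames <- ifelse(sess$phase == "baseline",
                     paste0("base", sess$session),
                     paste0("s", sess$session -
                              sum(sess$phase == "baseline")))
  r <- p <- matrix(NA_real_, nrow(sess), length(mcols),
                   dimnames = list(rowNames, mcols))
  for (i in seq_len(nrow(sess))) {
    sel <- behavior[behavior$session == sess$session[i], , drop = FALSE]
    intake <- setNames(sel$intake_ml, sel$animal_id)
    common <- intersect(names(intake), metrics$animal_id)
    if (length(common) < 4) next
    xv <- intake[common]
    for (j in seq_along(mcols)) {
      yv <- metrics[[mcols[j]]][match(common, metrics$animal_id)]
      ok <- is.finite(xv) & is.finite(yv)
      if (sum(ok) < 4 || length(unique(xv[ok])) == 1 ||
          length(unique(yv[ok])) == 1) next
      ct <- suppressWarnings(
        cor.test(xv[ok], yv[ok], method = "spearman", exact = FALSE))
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  q <- matrix(p.adjust(as.vector(p), method = "BH"), nrow(p),
              dimnames = dimnames(p))
  sig <- q <= alpha
  new("CorrelationMatrix", r = r, p = p, q = q, sig = sig, alpha = alpha)
}

#' Export a correlation matrix as a tidy table
#'
#' @param cm A [CorrelationMatrix-class].
#' @return data.frame with one row per (session, metric) cell.
#' @export
correlationTable <- function(cm) {
  stopifnot(is(cm, "CorrelationMatrix"))
  data.frame(session = rep(rownames(cm@r), ncol(cm@r)),
             metric = rep(colnames(cm@r), each = nrow(cm@r)),
             r = as.vector(cm@r), p = as.vector(cm@p),
             q = as.vector(cm@q), significant = as.vector(cm@sig))
}
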