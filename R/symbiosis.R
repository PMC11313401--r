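PHENO_COLS <- c("treatment", "variety", "rep", "nodules", "spad",
                "shoot_dw", "root_dw")

check_phenotypes <- function(table) {
  miss <- setdiff(PHENO_COLS, names(table))
  if (length(miss))
    stop("phenotype table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(table$nodules < 0)) stop("nodule counts must be >= 0", call. = FALSE)
  n_rep <- table(table$treatment, table$variety)
  if (any(n_rep[n_rep > 0] < 2))
    stop("each (treatment, variety) needs >= 2 replicates", call. = FALSE)
  invisible(table)
}

#' Standardise symbiotic indices against the best treatment mean
#'
#' Per bean variety, each treatment's mean nodule count, mean SPAD
#' (chlorophyll) and mean total dry biomass (shoot + root per plant) are
#' divided by the best treatment mean of that trait in the experiment, so
#' every index lies in `[0, 1]` with 1 for the best-performing treatment.
#' The uninoculated control (CK) takes part in the max scan like any other
#' treatment; having zero nodules, its nodulation index is 0.
#'
#' @param table phenotype data.frame with columns `treatment`, `variety`,
#'   `rep`, `nodules`, `spad`, `shoot_dw`, `root_dw`.
#' @return data.frame: `treatment`, `variety`, `nodule_index`,
#'   `chlorophyll_index`, `biomass_index`.
#' @export
standardize_indices <- function(table) {
  check_phenotypes(table)
  table$biomass <- table$shoot_dw + table$root_dw
  out <- lapply(unique(table$variety), function(v) {
    tv <- table[table$variety == v, ]
    agg <- stats::aggregate(tv[c("nodules", "spad", "biomass")],
                            by = list(treatment = tv$treatment), FUN = mean)
    idx <- function(x, what) {
      if (max(x) == 0) {
        message(sprintf("all %s means are zero for variety %s; index set to 0",
                        what, v))
        return(rep(0, length(x)))
      }
      x / max(x)
    }
    data.frame(treatment = agg$treatment, variety = v,
               nodule_index = idx(agg$nodules, "nodule"),
               chlorophyll_index = idx(agg$spad, "chlorophyll"),
               biomass_index = idx(agg$biomass, "biomass"),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Weighted composite symbiotic performance score
#'
#' `score = 100 * (0.25 * nodulation + 0.25 * chlorophyll + 0.5 * biomass)`,
#' each index in `[0, 1]`; the score is a percentage of the best achievable
#' performance and is monotone in every index.
#'
#' @param nodule,chlorophyll,biomass standardised indices in `[0, 1]`
#'   (vectorised).
#' @return score(s) in `[0, 100]`.
#' @examples
#' composite_score(0.8, 0.5, 0.6) # 62.5
#' @export
composite_score <- function(nodule, chlorophyll, biomass) {
  for (x in list(nodule, chlorophyll, biomass))
    if (any(x < 0 | x > 1 | is.na(x)))
      stop("indices must lie in [0, 1]", call. = FALSE)
  100 * (0.25 * nodule + 0.25 * chlorophyll + 0.5 * biomass)
}

#' One-way ANOVA with Fisher-LSD compact letter display
#'
#' Classical one-way ANOVA (between/within sums of squares) followed by
#' pairwise Fisher least-significant-difference t tests on the pooled
#' mean-square error, summarised as a compact letter display: treatments
#' sorted by descending mean, letters assigned by insert-and-absorb so that
#' two treatments share a letter iff they are not significantly different
#' at `alpha`. When every group has zero within-group variance the test is
#' degenerate and groups are lettered by exact mean equality (with a
#' message).
#'
#' @param values numeric response (replicate-level).
#' @param groups group labels, same length (>= 2 groups, each >= 2
#'   replicates).
#' @param alpha significance level (default 0.001).
#' @return data.frame sorted by descending mean: `group`, `mean`, `n`,
#'   `letters`; ANOVA statistics attached as attributes `f_value`,
#'   `p_value`, `mse`, `df_error`.
#' @export
anova_lsd <- function(values, groups, alpha = 0.001) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  n_i <- table(groups)
  if (length(n_i) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(n_i < 2)) stop("each group needs >= 2 replicates", call. = FALSE)
  fit <- aov(values ~ factor(groups))
  # a perfect fit (zero residual variance) is handled explicitly below;
  # muffle base R's unreliability warning for that case only
  an <- withCallingHandlers(anova(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  mse <- an["Residuals", "Mean Sq"]
  dfe <- an["Residuals", "Df"]
  means <- tapply(values, groups, mean)
  ord <- order(-means)
  g <- names(means)[ord]
  m <- as.numeric(means)[ord]
  n <- as.integer(n_i[g])
  k <- length(g)
  if (mse <= .Machine$double.eps * max(1, mean(values)^2)) {
    message("zero within-group variance everywhere; lettering by exact mean equality")
    differ <- outer(m, m, function(a, b) abs(a - b) > 0)
  } else {
    tcrit <- qt(1 - alpha / 2, dfe)
    se <- sqrt(mse * outer(1 / n, 1 / n, "+"))
    differ <- abs(outer(m, m, "-")) > tcrit * se
  }
  letters_out <- cld_insert_absorb(differ)
  out <- data.frame(group = g, mean = m, n = n, letters = letters_out,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "f_value") <- an[1, "F value"]
  attr(out, "p_value") <- an[1, "Pr(>F)"]
  attr(out, "mse") <- mse
  attr(out, "df_error") <- dfe
  out
}

# insert-and-absorb compact letter display from a logical "significantly
# different" matrix over groups already sorted by descending mean: start
# from one set holding every group, split each set containing a
# significantly different pair (keeping one copy without each member), then
# absorb redundant subsets; two groups share a letter iff not different
cld_insert_absorb <- function(differ) {
  k <- nrow(differ)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      if (!differ[i, j]) next
      hit <- vapply(sets, function(s) i %in% s && j %in% s, logical(1))
      if (!any(hit)) next
      split <- unlist(lapply(sets[hit], function(s)
        list(setdiff(s, i), setdiff(s, j))), recursive = FALSE)
      sets <- c(sets[!hit], split)
    }
  }
  sets <- sets[lengths(sets) > 0]
  sets <- unique(lapply(sets, sort))
  # absorb sets fully contained in another
  keep <- rep(TRUE, length(sets))
  for (a in seq_along(sets)) {
    for (b in seq_along(sets)) {
      if (a != b && keep[a] && keep[b] && all(sets[[a]] %in% sets[[b]]) &&
          length(sets[[a]]) < length(sets[[b]]))
        keep[a] <- FALSE
    }
  }
  sets <- sets[keep]
  # order letter sets by their first (best-mean) member for stable output
  sets <- sets[order(vapply(sets, min, integer(1)))]
  vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(sets, function(s) i %in% s, logical(1)))],
          collapse = "")
  }, character(1))
}

#' Treatment-to-control efficiency ratios
#'
#' Per variety, each treatment's mean total dry biomass and mean SPAD are
#' expressed relative to the uninoculated control mean (e.g. a planted
#' 2.8-fold biomass effect yields `biomass_ratio` 2.8 at zero noise). A
#' zero control mean leaves the ratio undefined (`NA`) and flagged.
#'
#' @param table phenotype data.frame (see [standardize_indices()]).
#' @param control control treatment label (default `"CK"`).
#' @return data.frame: `treatment`, `variety`, `biomass_ratio`,
#'   `chlorophyll_ratio`, `undefined`.
#' @export
efficiency_ratios <- function(table, control = "CK") {
  check_phenotypes(table)
  if (!control %in% table$treatment)
    stop(sprintf("control treatment '%s' not present", control), call. = FALSE)
  table$biomass <- table$shoot_dw + table$root_dw
  out <- lapply(unique(table$variety), function(v) {
    tv <- table[table$variety == v, ]
    agg <- stats::aggregate(tv[c("biomass", "spad")],
                            by = list(treatment = tv$treatment), FUN = mean)
    ck <- agg[agg$treatment == control, ]
    ratio <- function(x, ck_mean) if (ck_mean > 0) x / ck_mean else NA_real_
    data.frame(treatment = agg$treatment, variety = v,
               biomass_ratio = ratio(agg$biomass, ck$biomass),
               chlorophyll_ratio = ratio(agg$spad, ck$spad),
               undefined = ck$biomass <= 0 | ck$spad <= 0,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Score card: indices, composite score and significance letters
#'
#' Combines [standardize_indices()], [composite_score()] and [anova_lsd()]
#' per variety. For the letter display, a replicate-level score is formed
#' for every plant by standardising its raw values against the best
#' treatment means (so treatment means of the replicate scores equal the
#' composite score of the treatment indices), and the ANOVA + LSD runs on
#' those replicate scores.
#'
#' @param table phenotype data.frame (see [standardize_indices()]).
#' @param alpha significance level for the letter display (default 0.001).
#' @return data.frame: `treatment`, `variety`, the three indices, `score`,
#'   `letters`, sorted by variety then descending score.
#' @export
score_card <- function(table, alpha = 0.001) {
  idx <- standardize_indices(table)
  idx$score <- composite_score(idx$nodule_index, idx$chlorophyll_index,
                               idx$biomass_index)
  table$biomass <- table$shoot_dw + table$root_dw
  out <- lapply(unique(idx$variety), function(v) {
    tv <- table[table$variety == v, ]
    iv <- idx[idx$variety == v, ]
    best <- function(trait) {
      mx <- max(tapply(tv[[trait]], tv$treatment, mean))
      if (mx == 0) Inf else mx # trait degenerate -> contributes 0 below
    }
    bn <- best("nodules"); bc <- best("spad"); bb <- best("biomass")
    rep_score <- 100 * (0.25 * tv$nodules / bn + 0.25 * tv$spad / bc +
                          0.5 * tv$biomass / bb)
    lsd <- anova_lsd(rep_score, tv$treatment, alpha = alpha)
    iv$letters <- lsd$letters[match(iv$treatment, lsd$group)]
    iv[order(-iv$score), ]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
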