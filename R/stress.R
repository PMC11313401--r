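#' Abiotic-stress condition grids
#'
#' The five screening families with their ordered levels and control level:
#' pH 5-11 (control 7), NaCl 0.01-4 \% w/v (control 0.01), temperature
#' 4-45 degC (control 28), PEG 6000 0-15 \% w/v (control 0), glyphosate
#' 0-1.8 mL/L (control 0). `extreme` marks the harshest informative level
#' of each family, used as the ranking tie-break.
#'
#' @return named list per family: `levels`, `control`, `extreme`.
#' @export
condition_grids <- function() {
  list(
    pH          = list(levels = c(5, 6, 7, 8, 9, 10, 11), control = 7,  extreme = 11),
    NaCl        = list(levels = c(0.01, 1, 2, 3, 4),      control = 0.01, extreme = 2),
    temperature = list(levels = c(4, 10, 28, 37, 45),     control = 28, extreme = 45),
    PEG         = list(levels = c(0, 3, 5, 7, 10, 15),    control = 0,  extreme = 10),
    glyphosate  = list(levels = c(0, 0.6, 1.2, 1.8),      control = 0,  extreme = 1.8)
  )
}

#' Call growth per strain and condition level
#'
#' Compares each strain's mean growth measure at a level to its own control
#' level mean within the family: `normal` when the mean reaches
#' `normal_frac` of control, `none` when it is at or below `none_frac` of
#' control, `weak` in between. Strains whose control fails (control mean 0)
#' are excluded with a warning. Raising `normal_frac` can only shrink the
#' set of `normal` calls.
#'
#' @param observations data.frame with columns `strain`, `family`, `level`,
#'   `rep`, `growth` (>= 2 replicates per cell); levels must belong to the
#'   family's grid.
#' @param grids condition grids (default [condition_grids()]).
#' @param normal_frac,none_frac thresholds as fractions of the control mean
#'   (defaults 0.8 and 0.2).
#' @return data.frame of class `growth_calls`: `strain`, `family`, `level`,
#'   `mean_growth`, `call` (`normal`/`weak`/`none`).
#' @export
call_growth <- function(observations, grids = condition_grids(),
                        normal_frac = 0.8, none_frac = 0.2) {
  need <- c("strain", "family", "level", "rep", "growth")
  miss <- setdiff(need, names(observations))
  if (length(miss))
    stop("observations missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  stopifnot(normal_frac > none_frac)
  bad_fam <- setdiff(unique(observations$family), names(grids))
  if (length(bad_fam))
    stop("unknown condition family: ", paste(bad_fam, collapse = ", "),
         call. = FALSE)
  for (f in unique(observations$family)) {
    lv <- unique(observations$level[observations$family == f])
    bad <- setdiff(lv, grids[[f]]$levels)
    if (length(bad))
      stop(sprintf("unknown %s level(s): %s", f, paste(bad, collapse = ", ")),
           call. = FALSE)
  }
  cells <- stats::aggregate(growth ~ strain + family + level,
                            data = observations, FUN = mean)
  nrep <- stats::aggregate(growth ~ strain + family + level,
                           data = observations, FUN = length)
  if (any(nrep$growth < 2))
    stop("every (strain, family, level) cell needs >= 2 replicates",
         call. = FALSE)
  out <- lapply(split(cells, cells[c("strain", "family")], drop = TRUE),
                function(cf) {
    f <- cf$family[1]
    ctrl <- cf$growth[cf$level == grids[[f]]$control]
    if (length(ctrl) != 1)
      stop(sprintf("strain %s lacks the %s control level", cf$strain[1], f),
           call. = FALSE)
    if (ctrl <= 0) {
      warning(sprintf("strain %s excluded from %s: control mean is 0",
                      cf$strain[1], f), call. = FALSE)
      return(NULL)
    }
    cf$call <- ifelse(cf$growth >= normal_frac * ctrl, "normal",
                      ifelse(cf$growth <= none_frac * ctrl, "none", "weak"))
    cf
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  res <- res[order(res$strain, res$family, res$level),
             c("strain", "family", "level", "growth", "call")]
  names(res)[4] <- "mean_growth"
  rownames(res) <- NULL
  class(res) <- c("growth_calls", class(res))
  res
}

#' Summarise tolerance counts and per-strain breadth
#'
#' @param calls a [call_growth()] result covering the full grid for every
#'   strain retained.
#' @param grids condition grids (default [condition_grids()]).
#' @return list with `per_level` (data.frame: `family`, `level`,
#'   `n_normal`) and `per_strain` (data.frame: `strain`, `breadth` = number
#'   of non-control levels called normal, `extremes` = number of extreme
#'   levels called normal).
#' @export
summarize_tolerance <- function(calls, grids = condition_grids()) {
  ctrl <- vapply(grids, `[[`, numeric(1), "control")
  is_ctrl <- calls$level == ctrl[calls$family]
  per_level <- stats::aggregate(call ~ family + level, data = calls,
                                FUN = function(x) sum(x == "normal"))
  names(per_level)[3] <- "n_normal"
  per_level <- per_level[order(match(per_level$family, names(grids)),
                               per_level$level), ]
  rownames(per_level) <- NULL
  extreme <- vapply(grids, `[[`, numeric(1), "extreme")
  nc <- calls[!is_ctrl, ]
  per_strain <- data.frame(
    strain = sort(unique(calls$strain)),
    stringsAsFactors = FALSE)
  per_strain$breadth <- vapply(per_strain$strain, function(s)
    sum(nc$call[nc$strain == s] == "normal"), numeric(1))
  per_strain$extremes <- vapply(per_strain$strain, function(s) {
    cs <- calls[calls$strain == s, ]
    sum(cs$call == "normal" & cs$level == extreme[cs$family])
  }, numeric(1))
  list(per_level = per_level, per_strain = per_strain)
}

#' Rank strains by tolerance breadth
#'
#' Strains sort by breadth (non-control levels passed) descending, then by
#' number of extreme levels passed descending, then by strain id; the
#' ranking is invariant to input order.
#'
#' @param summary a [summarize_tolerance()] result.
#' @return data.frame: `rank`, `strain`, `breadth`, `extremes`.
#' @export
rank_tolerance <- function(summary) {
  ps <- summary$per_strain
  ps <- ps[order(-ps$breadth, -ps$extremes, ps$strain), ]
  data.frame(rank = seq_len(nrow(ps)), ps, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Select elite strains: efficient on both varieties and stress tolerant
#'
#' A strain is elite when it is in the top `k` of the composite symbiotic
#' score on *both* bean varieties and in the top `k` of the tolerance
#' ranking. An empty intersection returns an empty set (not an error).
#'
#' @param score_v1,score_v2 per-variety [score_card()] results (or any
#'   data.frame with `treatment` and `score`).
#' @param ranking a [rank_tolerance()] result covering the candidates.
#' @param k top-k cut for each screen (default 5).
#' @return character vector of elite strain ids (sorted).
#' @export
select_elite <- function(score_v1, score_v2, ranking, k = 5) {
  top_scores <- function(sc) {
    sc <- sc[sc$treatment != "CK", ]
    sc$treatment[order(-sc$score)][seq_len(min(k, nrow(sc)))]
  }
  top_tol <- ranking$strain[seq_len(min(k, nrow(ranking)))]
  sort(intersect(intersect(top_scores(score_v1), top_scores(score_v2)),
                 top_tol))
}
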