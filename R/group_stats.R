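# Rank statistics across age levels: Kruskal-Wallis comparisons with
# significance letters, and Spearman correlations within and between levels.
# Centrality values in a pen are neither normal nor independent in any
# parametric sense, and pens are small, so everything here is rank-based.

#' Kruskal-Wallis comparison of groups
#'
#' Tie-corrected Kruskal-Wallis rank test (chi-square approximation,
#' df = k - 1) with per-group median/range summaries.
#'
#' @param groups Named list of numeric vectors, one per group.
#' @return A `kw_result` list: `H`, `df`, `p_value`, and `summary` (tibble
#'   `group`, `n`, `median`, `min`, `max`). Identical values in all groups
#'   give `H = 0`, `p = 1`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) {
    abort("need at least two groups", class = "agonet_validation_error")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes == 0)) {
    abort(paste0("empty group: ", names(groups)[sizes == 0][1]),
          class = "agonet_validation_error")
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), sizes), levels = names(groups))
  if (length(unique(x)) == 1) {
    h <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(x, g)
    h <- unname(kt$statistic)
    p <- kt$p.value
  }
  structure(list(
    H = h, df = length(groups) - 1L, p_value = p,
    summary = tibble::tibble(
      group = names(groups), n = as.integer(sizes),
      median = vapply(groups, stats::median, numeric(1)),
      min = vapply(groups, min, numeric(1)),
      max = vapply(groups, max, numeric(1))
    )
  ), class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: X^2(%d) = %.4g, p %s\n",
              x$df, x$H, format_p_value(x$p_value)))
  print(x$summary)
  invisible(x)
}

#' Format a p-value in reporting style
#'
#' Values below 1e-4 are floored to `"< 0.0001"`; raw values are always kept
#' in the machine-readable outputs.
#'
#' @param p Numeric p-value(s).
#' @return Character vector.
#' @export
format_p_value <- function(p) {
  ifelse(p < 1e-4, "< 0.0001", paste0("= ", formatC(p, digits = 4, format = "f")))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (tie-safe), with the p-value from the
#' t approximation on n - 2 degrees of freedom. Degenerate inputs (fewer
#' than 3 pairs, or zero variance in a rank vector) return an `NA`
#' coefficient with a note instead of an error.
#'
#' @param x,y Numeric vectors of equal length. `NA` pairs are dropped.
#' @return List with `rho`, `p_value`, `n` (complete pairs), `note`
#'   (`NA_character_`, `"low_n"`, or `"zero_variance"`).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "agonet_validation_error")
  }
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, note = "low_n"))
  }
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, note = "zero_variance"))
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, note = NA_character_)
}

#' Significance letters for group comparisons
#'
#' Groups that do not differ significantly share a letter. If the global
#' Kruskal-Wallis test is non-significant all groups get `"a"`; otherwise
#' pairwise two-group Kruskal-Wallis tests (equivalent to rank-sum tests)
#' decide which groups differ, and letters are assigned by
#' insert-and-absorb so that two groups share a letter exactly when their
#' pairwise test is non-significant (intransitive patterns yield multi-letter
#' labels such as `"ab"`).
#'
#' @param groups Named list of numeric vectors.
#' @param alpha Pairwise significance level (default 0.05).
#' @param adjust `"none"` (default) or `"bonferroni"` for the pairwise
#'   p-values.
#' @return Named character vector of letter labels, one per group.
#' @export
assign_letters <- function(groups, alpha = 0.05, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  k <- length(groups)
  if (k == 1) return(stats::setNames("a", names(groups)))
  global <- kruskal_wallis(groups)
  if (global$p_value >= alpha) {
    return(stats::setNames(rep("a", k), names(groups)))
  }
  pairs <- utils::combn(k, 2)
  p_pair <- apply(pairs, 2, function(ij) {
    kruskal_wallis(groups[ij])$p_value
  })
  p_pair <- stats::p.adjust(p_pair, method = adjust)
  differ <- matrix(FALSE, k, k)
  for (c in seq_len(ncol(pairs))) {
    if (p_pair[c] < alpha) {
      differ[pairs[1, c], pairs[2, c]] <- TRUE
      differ[pairs[2, c], pairs[1, c]] <- TRUE
    }
  }
  # insert-and-absorb: start from one class of all groups, split on each
  # significantly different pair, drop classes contained in another
  classes <- list(seq_len(k))
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1, c]; j <- pairs[2, c]
    if (!differ[i, j]) next
    nxt <- list()
    for (cl in classes) {
      if (i %in% cl && j %in% cl) {
        nxt <- c(nxt, list(setdiff(cl, i)), list(setdiff(cl, j)))
      } else {
        nxt <- c(nxt, list(cl))
      }
    }
    keep <- rep(TRUE, length(nxt))
    for (a in seq_along(nxt)) {
      for (b in seq_along(nxt)) {
        if (a != b && keep[b] && all(nxt[[a]] %in% nxt[[b]]) &&
            (length(nxt[[a]]) < length(nxt[[b]]) || a > b)) {
          keep[a] <- FALSE
          break
        }
      }
    }
    classes <- nxt[keep]
  }
  classes <- classes[order(vapply(classes, min, numeric(1)))]
  labels <- vapply(seq_len(k), function(g) {
    paste0(letters[which(vapply(classes, function(cl) g %in% cl, logical(1)))],
           collapse = "")
  }, character(1))
  stats::setNames(labels, names(groups))
}

#' Compare centrality measures across age levels
#'
#' Runs a Kruskal-Wallis test per measure across the age levels, pooling
#' animals from all pens of a level as observations (the reporting unit is
#' the animal; an optional pen-median mode collapses each pen to its median
#' first to guard against pseudo-replication).
#'
#' @param records Centrality tibble from [centrality_table()].
#' @param measures Character vector of measure columns (default: all 14).
#' @param alpha Significance level for the letters.
#' @param pen_median Use pen medians instead of individual animals.
#' @param adjust Pairwise p-value adjustment for the letters.
#' @return A tibble with one row per (measure, level): `measure`, `level`,
#'   `n`, `median`, `min`, `max`, `letter`, plus the global `H`, `df`,
#'   `p_value` repeated within measure.
#' @export
compare_levels <- function(records, measures = MEASURE_COLS, alpha = 0.05,
                           pen_median = FALSE, adjust = "none") {
  levels_present <- intersect(age_levels(), unique(records$age_level))
  rows <- lapply(measures, function(m) {
    groups <- lapply(levels_present, function(lv) {
      v <- records[[m]][records$age_level == lv]
      if (pen_median) {
        v <- tapply(v, records$pen_id[records$age_level == lv], stats::median)
        v <- as.numeric(v)
      }
      v
    })
    names(groups) <- levels_present
    kw <- kruskal_wallis(groups)
    letters_ <- assign_letters(groups, alpha = alpha, adjust = adjust)
    dplyr::mutate(kw$summary,
                  measure = m, letter = unname(letters_[kw$summary$group]),
                  H = kw$H, df = kw$df, p_value = kw$p_value)
  })
  dplyr::bind_rows(rows) |>
    dplyr::rename(level = "group") |>
    dplyr::select("measure", "level", "n", "median", "min", "max",
                  "letter", "H", "df", "p_value")
}

# measure pairs reported within an age level: each measure's binary vs
# weighted variant, in- vs out-degree, degree family vs betweenness, and the
# degree family vs the matching closeness variants
within_level_pairs <- function() {
  base <- c("degree", "in_degree", "out_degree", "betweenness",
            "closeness", "in_closeness", "out_closeness")
  rbind(
    data.frame(var1 = paste0(base, "_binary"), var2 = paste0(base, "_weighted")),
    data.frame(var1 = "in_degree_binary", var2 = "out_degree_binary"),
    data.frame(var1 = c("degree_binary", "in_degree_binary", "out_degree_binary"),
               var2 = "betweenness_binary"),
    data.frame(var1 = c("degree_binary", "degree_binary", "degree_binary",
                        "in_degree_binary", "out_degree_binary"),
               var2 = c("closeness_binary", "in_closeness_binary",
                        "out_closeness_binary", "in_closeness_binary",
                        "out_closeness_binary"))
  )
}

#' Spearman correlations between measures within one age level
#'
#' Correlates the documented measure pairs (binary vs weighted variant of
#' each measure; in- vs out-degree; degree family vs betweenness; degree
#' family vs closeness family) over all animals of one age level, pooled
#' across pens.
#'
#' @param records Centrality tibble from [centrality_table()].
#' @param level One of [age_levels()].
#' @return Tibble `age_level`, `var1`, `var2`, `rho`, `p_value`, `n`,
#'   `note`.
#' @export
within_level_correlations <- function(records, level) {
  rec <- records[records$age_level == level, ]
  pairs <- within_level_pairs()
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- spearman_cor(rec[[pairs$var1[i]]], rec[[pairs$var2[i]]])
    tibble::tibble(age_level = level, var1 = pairs$var1[i],
                   var2 = pairs$var2[i], rho = r$rho,
                   p_value = r$p_value, n = r$n, note = r$note)
  })
  dplyr::bind_rows(rows)
}

#' Spearman correlations of measures between consecutive age levels
#'
#' For each consecutive level pair (weaned to growing, growing to gilts) and
#' each measure, correlates the values of the animals tracked at both levels
#' (paired by identity through the trajectory table). Animals absent from
#' either level of a pair are excluded from that pair.
#'
#' @param records Centrality tibble from [centrality_table()].
#' @param trajectories Trajectory tibble (see [read_trajectories()]).
#' @param measures Character vector of measure columns (default: all 14).
#' @return Tibble `level_from`, `level_to`, `measure`, `rho`, `p_value`,
#'   `n`, `note`.
#' @export
cross_level_correlations <- function(records, trajectories,
                                     measures = MEASURE_COLS) {
  lv <- age_levels()
  pen_col <- c(weaned = "weaned_pen", growing = "growing_pen", gilt = "gilt_pen")
  rows <- list()
  for (i in 1:2) {
    l1 <- lv[i]; l2 <- lv[i + 1]
    tracked <- trajectories[!is.na(trajectories[[pen_col[l1]]]) &
                              !is.na(trajectories[[pen_col[l2]]]), ]
    r1 <- records[records$age_level == l1,
                  c("animal_id", measures)][match(tracked$animal_id,
                    records$animal_id[records$age_level == l1]), ]
    r2 <- records[records$age_level == l2,
                  c("animal_id", measures)][match(tracked$animal_id,
                    records$animal_id[records$age_level == l2]), ]
    for (m in measures) {
      r <- spearman_cor(r1[[m]], r2[[m]])
      rows[[length(rows) + 1]] <- tibble::tibble(
        level_from = l1, level_to = l2, measure = m,
        rho = r$rho, p_value = r$p_value, n = r$n, note = r$note)
    }
  }
  dplyr::bind_rows(rows)
}
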