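## Dose-group statistics: one-way ANOVA, Tukey HSD significance
## matrices, and the cross-source accordance table comparing MTT, single
## component scores and the MLR predictions.

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups of observations")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- as.character(seq_along(groups))
  if (any(lengths(groups) < 2))
    stop("every group needs at least 2 observations")
  groups
}

groups_to_df <- function(groups) {
  data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), lengths(groups)),
               levels = names(groups)))
}

#' One-way analysis of variance across dose groups
#'
#' Classical fixed-effects one-way ANOVA (between/within decomposition);
#' the p-value comes from the F distribution.
#'
#' @param groups named list of numeric observation vectors, one per dose
#'   group (each of length >= 2)
#' @return list with \code{f_statistic}, \code{p_value}, the degrees of
#'   freedom and the sums of squares
#' @export
anova_oneway <- function(groups) {
  groups <- check_groups(groups)
  df <- groups_to_df(groups)
  k <- length(groups); N <- nrow(df)
  gm <- mean(df$y)
  ssb <- sum(lengths(groups) *
               (vapply(groups, mean, numeric(1)) - gm)^2)
  ssw <- sum((df$y - rep(vapply(groups, mean, numeric(1)),
                         lengths(groups)))^2)
  if (ssw == 0 && ssb == 0)
    stop("all observations identical; the F ratio is undefined")
  if (ssw == 0) {
    warning("zero within-group variance with unequal means; p = 0")
    return(list(f_statistic = Inf, p_value = 0,
                df_between = k - 1, df_within = N - k,
                ss_between = ssb, ss_within = ssw))
  }
  aov_tab <- stats::anova(stats::lm(y ~ g, data = df))
  list(f_statistic = aov_tab$`F value`[1],
       p_value = aov_tab$`Pr(>F)`[1],
       df_between = aov_tab$Df[1], df_within = aov_tab$Df[2],
       ss_between = aov_tab$`Sum Sq`[1], ss_within = aov_tab$`Sum Sq`[2])
}

#' Tukey HSD pairwise comparisons as a significance matrix
#'
#' All pairwise dose-group comparisons with studentized-range p-values
#' (classical equal-variance Tukey honest significant difference),
#' flagged at the two conventional levels: \code{"ns"} (p > 0.05),
#' \code{"*"} (p < 0.05), \code{"**"} (p < 0.01).
#'
#' @inheritParams anova_oneway
#' @param source label of the variable the groups carry (e.g.
#'   \code{"MTT"}, \code{"component 2"}, \code{"MLR@PARAFAC"})
#' @return object of class \code{significance_matrix}: symmetric p-value
#'   and flag matrices over the group labels
#' @export
tukey_hsd <- function(groups, source = NA_character_) {
  groups <- check_groups(groups)
  df <- groups_to_df(groups)
  if (stats::var(df$y) == 0)
    stop("all observations identical; pairwise comparisons are undefined")
  labs <- names(groups)
  k <- length(labs)
  p <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  if (sum((df$y - rep(vapply(groups, mean, numeric(1)),
                      lengths(groups)))^2) == 0) {
    warning("zero within-group variance; unequal means flagged at p = 0")
    means <- vapply(groups, mean, numeric(1))
    for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
      p[i, j] <- if (means[i] == means[j]) 1 else 0
  } else {
    th <- stats::TukeyHSD(stats::aov(y ~ g, data = df))$g
    pairs <- strsplit(rownames(th), "-", fixed = TRUE)
    for (r in seq_len(nrow(th))) {
      i <- pairs[[r]][1]; j <- pairs[[r]][2]
      p[i, j] <- p[j, i] <- th[r, "p adj"]
    }
  }
  significance_matrix(p, source = source)
}

significance_matrix <- function(p, source = NA_character_) {
  stopifnot(is.matrix(p), nrow(p) == ncol(p))
  flags <- matrix(NA_character_, nrow(p), ncol(p), dimnames = dimnames(p))
  off <- !is.na(p)
  flags[off] <- ifelse(p[off] < 0.01, "**",
                       ifelse(p[off] < 0.05, "*", "ns"))
  structure(list(labels = rownames(p), p_values = p, flags = flags,
                 source = source),
            class = "significance_matrix")
}

#' @export
print.significance_matrix <- function(x, ...) {
  cat("Pairwise Tukey HSD",
      if (!is.na(x$source)) paste0("(", x$source, ")"), "\n")
  print(noquote(ifelse(is.na(x$flags), ".", x$flags)))
  invisible(x)
}

#' Write / read a significance matrix as CSV
#'
#' Long-format CSV (\code{group_a}, \code{group_b}, \code{p_value},
#' \code{flag}) that round-trips losslessly through
#' \code{read_significance_matrix}.
#'
#' @param x a \code{significance_matrix}
#' @param path CSV path
#' @return invisibly, the path (writer) / the matrix (reader)
#' @export
write_significance_matrix <- function(x, path) {
  stopifnot(inherits(x, "significance_matrix"))
  labs <- x$labels
  idx <- which(upper.tri(x$p_values), arr.ind = TRUE)
  out <- data.frame(
    group_a = labs[idx[, 1]], group_b = labs[idx[, 2]],
    # full-precision decimal text so the round trip is bit-exact
    p_value = sprintf("%.17g", x$p_values[idx]), flag = x$flags[idx],
    stringsAsFactors = FALSE)
  utils::write.csv(cbind(source = x$source, out), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_significance_matrix
#' @param path CSV path written by \code{write_significance_matrix}
#' @export
read_significance_matrix <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(group_a = "character",
                                        group_b = "character"))
  labs <- unique(c(tab$group_a, tab$group_b))
  k <- length(labs)
  p <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  for (r in seq_len(nrow(tab)))
    p[tab$group_a[r], tab$group_b[r]] <-
      p[tab$group_b[r], tab$group_a[r]] <- tab$p_value[r]
  significance_matrix(p, source = tab$source[1])
}

#' Significance tables across measurement sources
#'
#' Computes one Tukey HSD significance matrix per source — the MTT
#' reference, each PARAFAC component's scores, and the MLR predictions —
#' over the same dose labels, and lists the pairs on which any
#' score-based source disagrees with MTT. The interesting disagreements
#' are pairs the fluorescence route separates although MTT cannot
#' (higher sensitivity) and vice versa (lost discrimination).
#'
#' @param mtt_groups named list of MTT viability vectors per dose
#' @param score_groups list over components; each element a named list of
#'   score vectors per dose with the same labels as \code{mtt_groups}
#' @param prediction_groups named list of MLR-predicted viability vectors
#'   per dose, same labels
#' @return object of class \code{accordance_tables}: list of
#'   \code{significance_matrix} objects (\code{$mtt},
#'   \code{$components}, \code{$mlr}) and a \code{disagreements}
#'   data.frame (source, pair, MTT flag, source flag)
#' @export
accordance_tables <- function(mtt_groups, score_groups,
                              prediction_groups) {
  labs <- names(check_groups(mtt_groups))
  check_labels <- function(g, what) {
    if (!identical(sort(names(g)), sort(labs)))
      stop("dose labels of ", what, " do not match the MTT groups")
    g[labs]
  }
  mtt <- tukey_hsd(mtt_groups, source = "MTT")
  comps <- lapply(seq_along(score_groups), function(f)
    tukey_hsd(check_labels(score_groups[[f]], paste("component", f)),
              source = paste("component", f)))
  names(comps) <- paste0("component_", seq_along(score_groups))
  mlr <- tukey_hsd(check_labels(prediction_groups, "MLR predictions"),
                   source = "MLR@PARAFAC")
  dis <- list()
  sig <- function(m, i, j) m$p_values[i, j] < 0.05
  for (src in c(comps, list(mlr))) {
    for (i in seq_along(labs)) for (j in seq_along(labs)) {
      if (j <= i) next
      a <- sig(mtt, i, j); b <- sig(src, i, j)
      if (a != b)
        dis[[length(dis) + 1]] <- data.frame(
          source = src$source, group_a = labs[i], group_b = labs[j],
          mtt_flag = mtt$flags[i, j], source_flag = src$flags[i, j],
          direction = if (b) "source more sensitive" else
            "source less sensitive",
          stringsAsFactors = FALSE)
    }
  }
  structure(list(mtt = mtt, components = comps, mlr = mlr,
                 disagreements = if (length(dis)) do.call(rbind, dis)
                 else data.frame()),
            class = "accordance_tables")
}

#' @export
print.accordance_tables <- function(x, ...) {
  print(x$mtt); for (m in x$components) print(m); print(x$mlr)
  if (nrow(x$disagreements)) {
    cat("Disagreements with MTT:\n")
    print(x$disagreements, row.names = FALSE)
  } else cat("No disagreements with MTT\n")
  invisible(x)
}
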