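# Statistical layer: normality, mixed repeated-measures ANOVA, t-tests --------

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over the standard Shapiro-Wilk implementation (Royston's
#' approximation), with the sample-size and degeneracy preconditions made
#' explicit.
#'
#' @param x Numeric sample, 3 <= n <= 5000, non-constant.
#' @return List: `w` statistic, `p` value.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  .check(length(x) >= 3 && length(x) <= 5000,
         "Shapiro-Wilk requires 3 <= n <= 5000")
  .check(stats::sd(x) > 0, "Shapiro-Wilk is undefined for a constant sample")
  ht <- stats::shapiro.test(x)
  list(w = unname(ht$statistic), p = ht$p.value)
}

#' Pooled-variance unpaired t-test
#'
#' Student's two-sided unpaired t-test with pooled variance. Two identical
#' degenerate samples (zero pooled variance, equal means) give `t = 0, p = 1`;
#' zero pooled variance with unequal means is an error.
#'
#' @param a,b Numeric samples, each n >= 2.
#' @return List: `t`, `df`, `p`.
#' @export
unpaired_t_test <- function(a, b) {
  .check(length(a) >= 2 && length(b) >= 2, "each sample needs n >= 2")
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  if (pooled_var == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    stop("zero pooled variance with unequal means: t is undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` for a family of `m` comparisons; order-preserving and
#' never smaller than the raw p-value.
#'
#' @param p_values Raw p-values.
#' @param m Family size, `m >= max(1, length(p_values))`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  .check(m >= 1, "m must be >= 1")
  .check(m >= length(p_values), "m must be at least the number of p-values")
  pmin(1, p_values * m)
}

#' Mixed (split-plot) two-way repeated-measures ANOVA
#'
#' Between-subject factor `group` (e.g. control vs FGR, possibly unbalanced),
#' within-subject factor `state` (every subject measured in every state).
#' The decomposition is the classical split-plot one: in the between stratum,
#' the group effect is tested against subject-within-group variation (a
#' single between factor, so Type I and Type III sums of squares coincide);
#' in the within stratum, state and the group x state interaction are tested
#' against the state x subject-within-group residual. With two states there
#' is no sphericity question, so no epsilon correction is applied. Pairwise
#' cell comparisons (for 2 x 2 designs) are the four implied by the study
#' figures - group within each state (unpaired, pooled variance) and state
#' within each group (paired) - Bonferroni-adjusted with m = 4.
#'
#' @param data Data frame with columns `subject`, `group`, `state` and the
#'   response (`value` by default).
#' @param value Name of the response column.
#' @param pairwise Compute the pairwise table (default `TRUE` for 2 x 2
#'   designs).
#' @param alpha Significance level for the pairwise flags (default 0.05).
#' @return An `anova_result` list: `f_group`, `f_state`, `f_interaction`,
#'   `df` (named list of numerator/denominator df pairs), `p_group`,
#'   `p_state`, `p_interaction`, `ss` (component sums of squares), and
#'   `pairwise` (data frame or `NULL`).
#' @export
mixed_anova <- function(data, value = "value", pairwise = TRUE,
                        alpha = 0.05) {
  .check(all(c("subject", "group", "state", value) %in% names(data)),
         "data needs columns subject, group, state and the response")
  y <- data[[value]]
  .check(is.numeric(y) && !anyNA(y), "response must be numeric without NAs")
  subject <- as.character(data$subject)
  group <- as.character(data$group)
  state <- as.character(data$state)
  states <- sort(unique(state))
  s <- length(states)
  .check(s >= 2, "need at least two states")

  # repeated-measures structure: each subject appears once per state
  tab <- table(subject, state)
  bad <- rownames(tab)[apply(tab, 1, function(r) any(r != 1))]
  if (length(bad) > 0)
    stop("subject(s) without exactly one observation per state: ",
         paste(bad, collapse = ", "), call. = FALSE)
  subj_group <- tapply(group, subject, function(g) unique(g)[1])
  .check(all(tapply(group, subject, function(g) length(unique(g))) == 1),
         "a subject cannot change group")
  groups <- sort(unique(group))
  n_g <- table(factor(subj_group, levels = groups))
  .check(all(n_g >= 2), "need at least 2 subjects per group")
  n_subj <- length(unique(subject))

  grand <- mean(y)
  subj_mean <- tapply(y, subject, mean)
  grp_mean <- tapply(y, group, mean)
  st_mean <- tapply(y, state, mean)
  cell_mean <- tapply(y, list(group, state), mean)

  ss_group <- s * sum(n_g * (grp_mean[groups] - grand)^2)
  ss_e1 <- s * sum((subj_mean - grp_mean[subj_group[names(subj_mean)]])^2)
  ss_state <- n_subj * sum((st_mean - grand)^2)
  ss_int <- 0
  for (g in groups) for (j in states)
    ss_int <- ss_int + n_g[[g]] *
      (cell_mean[g, j] - grp_mean[[g]] - st_mean[[j]] + grand)^2
  ss_total <- sum((y - grand)^2)
  ss_e2 <- ss_total - ss_group - ss_e1 - ss_state - ss_int

  df_group <- length(groups) - 1
  df_e1 <- n_subj - length(groups)
  df_state <- s - 1
  df_int <- df_group * df_state
  df_e2 <- df_e1 * df_state
  .check(df_e1 > 0 && df_e2 > 0, "zero error degrees of freedom")

  ms <- function(ss, df) ss / df
  f_group <- ms(ss_group, df_group) / ms(ss_e1, df_e1)
  f_state <- ms(ss_state, df_state) / ms(ss_e2, df_e2)
  f_int <- ms(ss_int, df_int) / ms(ss_e2, df_e2)

  res <- structure(list(
    f_group = f_group, f_state = f_state, f_interaction = f_int,
    df = list(group = c(df_group, df_e1), state = c(df_state, df_e2),
              interaction = c(df_int, df_e2)),
    p_group = stats::pf(f_group, df_group, df_e1, lower.tail = FALSE),
    p_state = stats::pf(f_state, df_state, df_e2, lower.tail = FALSE),
    p_interaction = stats::pf(f_int, df_int, df_e2, lower.tail = FALSE),
    ss = c(group = ss_group, subject_within_group = ss_e1,
           state = ss_state, interaction = ss_int,
           state_by_subject = ss_e2, total = ss_total),
    pairwise = NULL), class = "anova_result")

  if (pairwise && length(groups) == 2 && s == 2) {
    res$pairwise <- .pairwise_cells(y, subject, group, state, groups, states,
                                    alpha)
  }
  res
}

# The four cell comparisons of a 2 x 2 mixed design, Bonferroni m = 4.
.pairwise_cells <- function(y, subject, group, state, groups, states, alpha) {
  rows <- list()
  for (j in states) {
    a <- y[group == groups[1] & state == j]
    b <- y[group == groups[2] & state == j]
    tt <- unpaired_t_test(a, b)
    rows[[length(rows) + 1]] <- data.frame(
      comparison = sprintf("%s vs %s @ %s", groups[1], groups[2], j),
      estimate = mean(a) - mean(b), t = tt$t, df = tt$df, p_raw = tt$p,
      stringsAsFactors = FALSE)
  }
  for (g in groups) {
    sel <- group == g
    subj <- unique(subject[sel])
    d <- vapply(subj, function(sb) {
      y[sel & subject == sb & state == states[2]] -
        y[sel & subject == sb & state == states[1]]
    }, numeric(1))
    if (stats::sd(d) == 0) {
      tt <- list(t = if (mean(d) == 0) 0 else Inf,
                 df = length(d) - 1,
                 p = if (mean(d) == 0) 1 else 0)
    } else {
      ht <- stats::t.test(d)
      tt <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value)
    }
    rows[[length(rows) + 1]] <- data.frame(
      comparison = sprintf("%s vs %s @ %s", states[2], states[1], g),
      estimate = mean(d), t = tt$t, df = tt$df, p_raw = tt$p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni(out$p_raw, m = nrow(out))
  out$significant <- out$p_adj < alpha
  out
}

#' Run the statistical layer over every variable of a cohort table
#'
#' For each requested column, runs the mixed repeated-measures ANOVA across
#' group and state, collecting the three p-values (group, state,
#' group x state) and the Bonferroni pairwise table.
#'
#' @param cohort Data frame with `subject`, `group`, `state` and variable
#'   columns.
#' @param variables Character vector of columns to analyse.
#' @return List: `table` (one row per variable: F and p per effect) and
#'   `pairwise` (one row per variable x comparison).
#' @export
analyse_variables <- function(cohort, variables) {
  missing <- setdiff(variables, names(cohort))
  .check(length(missing) == 0,
         paste("variables not in cohort:", paste(missing, collapse = ", ")))
  rows <- list()
  prs <- list()
  for (v in variables) {
    a <- mixed_anova(cohort, value = v)
    rows[[v]] <- data.frame(
      variable = v, f_group = a$f_group, p_group = a$p_group,
      f_state = a$f_state, p_state = a$p_state,
      f_interaction = a$f_interaction, p_interaction = a$p_interaction,
      stringsAsFactors = FALSE)
    if (!is.null(a$pairwise)) {
      pr <- a$pairwise
      pr$variable <- v
      prs[[v]] <- pr
    }
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       pairwise = do.call(rbind, c(prs, list(make.row.names = FALSE))))
}
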