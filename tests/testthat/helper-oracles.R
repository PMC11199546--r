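# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force geometry for the mask erosion, the
# classical Error()-stratum aov fit for the split-plot ANOVA, and closed-form
# integrals for the flow phantoms.

# Distance from every TRUE pixel to the nearest FALSE pixel (grid-limited),
# by exhaustive search.
brute_dist_to_boundary <- function(mask) {
  d <- matrix(0, nrow(mask), ncol(mask))
  bg <- which(!mask, arr.ind = TRUE)
  fg <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    dr <- bg[, 1] - fg[i, 1]
    dc <- bg[, 2] - fg[i, 2]
    d[fg[i, 1], fg[i, 2]] <- sqrt(min(dr * dr + dc * dc))
  }
  d
}

# Reference central-fraction erosion: rank by depth, tie-break by row-major
# pixel index, keep max(1, floor(fraction * n)).
brute_erode <- function(mask, fraction) {
  d <- brute_dist_to_boundary(mask)
  idx <- which(mask)
  rowmajor <- (row(mask)[idx] - 1L) * ncol(mask) + col(mask)[idx]
  ord <- order(-d[idx], rowmajor)
  keep <- idx[ord[seq_len(max(1L, floor(fraction * length(idx))))]]
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[keep] <- TRUE
  out
}

# Split-plot ANOVA oracle via stats::aov with an Error(subject) stratum.
aov_oracle <- function(df) {
  df$subject <- factor(df$subject)
  df$group <- factor(df$group)
  df$state <- factor(df$state)
  s <- summary(stats::aov(value ~ group * state + Error(subject), data = df))
  b <- s[["Error: subject"]][[1]]
  w <- s[["Error: Within"]][[1]]
  list(f_group = b["group", "F value"],
       p_group = b["group", "Pr(>F)"],
       f_state = w["state", "F value"],
       p_state = w["state", "Pr(>F)"],
       f_interaction = w["group:state", "F value"],
       p_interaction = w["group:state", "Pr(>F)"])
}

# Random small mixed design: G groups x s states, n_g subjects per group.
random_design <- function(seed, n_groups = 2, n_states = 2, n_range = 2:6,
                          effects = TRUE) {
  set.seed(seed)
  n_g <- n_range[sample.int(length(n_range), n_groups, replace = TRUE)]
  subs <- sprintf("s%03d", seq_len(sum(n_g)))
  grp <- rep(paste0("g", seq_len(n_groups)), n_g)
  df <- expand.grid(subject = subs, state = paste0("st", seq_len(n_states)),
                    stringsAsFactors = FALSE)
  df$group <- grp[match(df$subject, subs)]
  mu <- if (effects) {
    stats::rnorm(1) +
      stats::rnorm(n_groups)[match(df$group, unique(grp))] +
      stats::rnorm(n_states)[match(df$state, unique(df$state))]
  } else 0
  u <- stats::rnorm(length(subs))
  df$value <- mu + u[match(df$subject, subs)] + stats::rnorm(nrow(df))
  df
}

# Mixed design generator on the 12-vs-9 study layout with a configurable
# group x state interaction (delta, in SD units) applied to the FGR-normoxia
# cell only; subject intercept carries half the variance.
study_design_sim <- function(seed, delta = 0, n_control = 12, n_fgr = 9) {
  set.seed(seed)
  n <- n_control + n_fgr
  subs <- sprintf("s%02d", seq_len(n))
  grp <- rep(c("control", "FGR"), c(n_control, n_fgr))
  df <- expand.grid(subject = subs, state = c("normoxia", "hypoxia"),
                    stringsAsFactors = FALSE)
  df$group <- grp[match(df$subject, subs)]
  u <- stats::rnorm(n, 0, sqrt(0.5))
  df$value <- u[match(df$subject, subs)] +
    stats::rnorm(nrow(df), 0, sqrt(0.5)) -
    delta * (df$group == "FGR" & df$state == "normoxia")
  df
}

# Full flow-vessel set helper for circulation tests.
full_flows <- function(UV = 250, DV = 70, AAo = 220, DA = 250, DAo = 330,
                       SVC = 130, LPA = 35, RPA = 35, CCA_left = 30,
                       CCA_right = 30, MPA = DA + LPA + RPA) {
  c(UV = UV, DV = DV, AAo = AAo, MPA = MPA, DA = DA, DAo = DAo, SVC = SVC,
    LPA = LPA, RPA = RPA, CCA_left = CCA_left, CCA_right = CCA_right)
}
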