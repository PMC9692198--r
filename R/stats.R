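# Group-level statistics: global connectivity curves (Kruskal-Wallis),
# edge-wise one-tailed Wilcoxon networks with Benjamini-Hochberg
# correction and network density K, rank-biserial effect sizes, region
# summaries, spindle-removal contrast, and trajectory comparisons.

# Per-subject global means from an n x p x p array (NA cells skipped).
subject_global_means <- function(arr) {
  apply(arr, 1, function(m) mean(m[upper.tri(m)], na.rm = TRUE))
}

#' Global mean connectivity with Kruskal-Wallis tests
#'
#' For each band: per-subject global mean over unmasked edges, group
#' means, and a Kruskal-Wallis test across groups.
#'
#' @param conn named list of bands; each element an `n_subjects x p x p`
#'   array (subject order matching `manifest`), or a single array for
#'   one band.
#' @param manifest data.frame with a `subject` column and the grouping
#'   column.
#' @param grouping manifest column with group labels (>= 2 groups,
#'   each n >= 2).
#' @return list: `curves` (data.frame `band`, `group`, `mean`, `n`),
#'   `tests` (data.frame `band`, `H`, `p`),
#'   `subject_means` (data.frame `band`, `subject`, `group`, `mean`).
#' @export
global_mean_connectivity <- function(conn, manifest, grouping = "neuro_2y") {
  if (is.array(conn) && length(dim(conn)) == 3) conn <- list(band1 = conn)
  labs <- as.character(manifest[[grouping]])
  tab <- table(labs)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with n >= 2 each")
  curves <- NULL; tests <- NULL; subj <- NULL
  for (b in names(conn)) {
    gm <- subject_global_means(conn[[b]])
    if (any(!is.finite(gm))) stop("a group was emptied by masking")
    if (var(gm) < 1e-24) {
      # all subjects tied: tie-corrected statistic degenerates to H = 0
      tests <- rbind(tests, data.frame(band = b, H = 0, p = 1))
    } else {
      kw <- kruskal.test(gm, factor(labs))
      tests <- rbind(tests, data.frame(band = b, H = unname(kw$statistic),
                                       p = kw$p.value))
    }
    agg <- aggregate(gm, list(group = labs), mean)
    curves <- rbind(curves, data.frame(band = b, group = agg$group,
                                       mean = agg$x,
                                       n = as.integer(tab[agg$group])))
    subj <- rbind(subj, data.frame(band = b, subject = manifest$subject,
                                   group = labs, mean = gm))
  }
  list(curves = curves, tests = tests, subject_means = subj)
}

# One-tailed Wilcoxon rank-sum p-value for alternative x > y.
# Exact when min(n) <= 10 and no ties; tie-corrected normal otherwise.
rank_sum_p <- function(x, y) {
  if (sd(c(x, y)) < 1e-14) return(1)   # constant edge across all subjects
  suppressWarnings(
    wilcox.test(x, y, alternative = "greater",
                exact = min(length(x), length(y)) <= 10,
                correct = TRUE)$p.value)
}

#' Rank-biserial effect size
#'
#' `(wins_A - wins_B) / (n_A * n_B)` over all cross-group pairs, ties
#' counted half to each side; equivalently `1 - 2 U_B / (n_A n_B)`.
#' Ranges over `[-1, 1]`; 1 means complete separation `x > y`.
#'
#' @param x,y numeric samples for groups A and B.
#' @return scalar in `[-1, 1]`.
#' @export
effect_size <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  r <- rank(c(x, y))
  n1 <- length(x); n2 <- length(y)
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # wins of x (ties halved)
  U2 <- n1 * n2 - U1
  (U1 - U2) / (n1 * n2)
}

#' Edge-wise group comparison
#'
#' One-tailed Wilcoxon rank-sum test per unmasked edge for the
#' alternative A > B, Benjamini-Hochberg correction over all unmasked
#' edges, network density `K` (significant / unmasked), and per-edge
#' rank-biserial effect sizes.
#'
#' @param a,b arrays `n_subjects x p x p` for groups A and B (each
#'   n >= 3); masked (`NA`) cells must agree between groups.
#' @param alpha BH false-discovery level.
#' @param band,mode metadata carried into the result.
#' @param direction label for the alternative, default `"A>B"`.
#' @return a `group_comparison`: `p` (raw p matrix), `significant`
#'   (logical matrix after BH), `effect` (effect-size matrix), `K`,
#'   `n_significant`, `n_edges`, `alpha`, `direction`, `band`, `mode`,
#'   `n` (group sizes).
#' @export
edgewise_comparison <- function(a, b, alpha = 0.05, band = NA, mode = NA,
                                direction = "A>B") {
  stopifnot(length(dim(a)) == 3, length(dim(b)) == 3,
            all(dim(a)[-1] == dim(b)[-1]))
  if (dim(a)[1] < 3 || dim(b)[1] < 3) stop("each group needs n >= 3")
  p_dim <- dim(a)[2]
  maskA <- apply(a, c(2, 3), function(v) any(is.na(v)))
  maskB <- apply(b, c(2, 3), function(v) any(is.na(v)))
  if (!identical(maskA, maskB)) stop("edges not masked consistently")
  ut <- which(upper.tri(matrix(0, p_dim, p_dim)) & !maskA)
  pmat <- matrix(NA_real_, p_dim, p_dim)
  emat <- matrix(NA_real_, p_dim, p_dim)
  for (k in ut) {
    ij <- arrayInd(k, c(p_dim, p_dim))
    xa <- a[, ij[1], ij[2]]; xb <- b[, ij[1], ij[2]]
    pmat[k] <- rank_sum_p(xa, xb)
    emat[k] <- effect_size(xa, xb)
  }
  padj <- p.adjust(pmat[ut], method = "BH")
  sig <- matrix(NA, p_dim, p_dim)
  sig[ut] <- padj <= alpha
  # symmetrize
  pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]
  emat[lower.tri(emat)] <- t(emat)[lower.tri(emat)]
  sig[lower.tri(sig)] <- t(sig)[lower.tri(sig)]
  nsig <- sum(sig[ut], na.rm = TRUE)
  structure(list(p = pmat, significant = sig, effect = emat,
                 K = nsig / length(ut), n_significant = nsig,
                 n_edges = length(ut), alpha = alpha,
                 direction = direction, band = band, mode = mode,
                 n = c(A = dim(a)[1], B = dim(b)[1])),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (%s, band %s): K = %.4f (%d / %d edges, BH alpha = %g)\n",
              x$direction, ifelse(is.na(x$mode), "?", x$mode),
              ifelse(is.na(x$band), "?", format(x$band)), x$K,
              x$n_significant, x$n_edges, x$alpha))
  invisible(x)
}

#' Regional summaries of a difference network
#'
#' Node involvement per region (fraction of possible edges incident to
#' the region's parcels that are significant), per region-pair edge
#' fractions, and the Euclidean centroid distances of the significant
#' edges (reported on a natural scale; plot on log).
#'
#' @param comp a `group_comparison`.
#' @param bundle the `lead_field_bundle` providing parcel regions and
#'   centroids.
#' @return list: `node_involvement` (data.frame `region`, `fraction`),
#'   `region_pairs` (data.frame `region_a`, `region_b`, `fraction`),
#'   `edge_lengths` (numeric), `interhemispheric_fraction`.
#' @export
region_summaries <- function(comp, bundle) {
  stopifnot(inherits(comp, "group_comparison"),
            inherits(bundle, "lead_field_bundle"))
  p <- nrow(comp$significant)
  if (p != bundle$n_parcels) stop("bundle parcel count mismatch")
  reg <- bundle$regions$region
  hemi <- bundle$regions$hemisphere
  sig <- comp$significant
  ut <- upper.tri(sig)
  usable <- ut & !is.na(sig)
  regions <- sort(unique(reg))
  node_inv <- data.frame(region = regions, fraction = vapply(regions, function(r) {
    inc <- outer(reg == r, rep(TRUE, p), `&`) | outer(rep(TRUE, p), reg == r, `&`)
    poss <- usable & inc
    if (!any(poss)) return(0)
    sum(sig[poss]) / sum(poss)
  }, numeric(1)))
  rp <- expand.grid(region_a = regions, region_b = regions,
                    stringsAsFactors = FALSE)
  rp <- rp[as.integer(factor(rp$region_a, regions)) <=
             as.integer(factor(rp$region_b, regions)), ]
  rp$fraction <- mapply(function(ra, rb) {
    between <- (outer(reg == ra, reg == rb, `&`) |
                  outer(reg == rb, reg == ra, `&`))
    poss <- usable & between
    if (!any(poss)) return(0)
    sum(sig[poss]) / sum(poss)
  }, rp$region_a, rp$region_b)
  sig_idx <- which(usable & sig, arr.ind = TRUE)
  lengths <- if (nrow(sig_idx)) sqrt(rowSums(
    (bundle$centroids[sig_idx[, 1], , drop = FALSE] -
       bundle$centroids[sig_idx[, 2], , drop = FALSE])^2)) else numeric(0)
  inter <- if (nrow(sig_idx))
    mean(hemi[sig_idx[, 1]] != hemi[sig_idx[, 2]]) else 0
  list(node_involvement = node_inv, region_pairs = rp,
       edge_lengths = lengths, interhemispheric_fraction = inter)
}

#' Spindle-removal contrast
#'
#' Pairs the group comparisons computed on the full data with those
#' computed after spindle excision on the same subjects, and reports the
#' change in network density and in the global group difference per
#' band.
#'
#' @param full,removed named lists (by band) of `group_comparison`
#'   objects from identical subject sets.
#' @param means_full,means_removed optional outputs of
#'   [global_mean_connectivity()] for the same two variants, used for
#'   the global-difference delta.
#' @return data.frame `band`, `K_full`, `K_removed`, `dK` (and
#'   `d_group_diff` when means are supplied).
#' @export
spindle_removal_contrast <- function(full, removed, means_full = NULL,
                                     means_removed = NULL) {
  stopifnot(identical(names(full), names(removed)))
  out <- data.frame(band = names(full),
                    K_full = vapply(full, function(x) x$K, numeric(1)),
                    K_removed = vapply(removed, function(x) x$K, numeric(1)))
  for (b in names(full)) {
    nf <- full[[b]]$n; nr <- removed[[b]]$n
    if (!identical(nf, nr)) stop("subject sets differ between variants")
  }
  out$dK <- out$K_removed - out$K_full
  if (!is.null(means_full) && !is.null(means_removed)) {
    gd <- function(mm, b) {
      cv <- mm$curves[mm$curves$band == b, ]
      max(cv$mean) - min(cv$mean)
    }
    out$d_group_diff <- vapply(out$band, function(b)
      gd(means_removed, b) - gd(means_full, b), numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Trajectory-group analysis
#'
#' Groups subjects by their neurocognitive trajectory (`"<1y>-<2y>"`),
#' drops groups below `min_n` (with a message), summarizes per-group
#' global connectivity per band, and runs one-tailed rank-sum tests (in
#' both directions, BH-corrected across bands) between trajectory groups
#' sharing the same 1-year label.
#'
#' @param conn named list (by band) of `n_subjects x p x p` arrays
#'   (subject order matching `manifest`).
#' @param manifest data.frame with `subject` and `trajectory` columns
#'   (see [cohort_manifest()]).
#' @param min_n minimum subjects per trajectory group.
#' @param alpha BH level.
#' @return list: `summaries` (data.frame `band`, `trajectory`, `mean`,
#'   `n`), `tests` (data.frame `band`, `group_a`, `group_b`,
#'   `direction`, `p`, `p_adj`, `effect`), `dropped` (labels removed).
#' @export
trajectory_analysis <- function(conn, manifest, min_n = 2, alpha = 0.05) {
  stopifnot("trajectory" %in% names(manifest))
  if (is.array(conn) && length(dim(conn)) == 3) conn <- list(band1 = conn)
  traj <- as.character(manifest$trajectory)
  tab <- table(traj)
  dropped <- names(tab[tab < min_n])
  if (length(dropped))
    message("dropping trajectory groups below n = ", min_n, ": ",
            paste(dropped, collapse = ", "))
  keep_lab <- setdiff(names(tab), dropped)
  summaries <- NULL; tests <- NULL
  first_of <- function(lab) strsplit(lab, "-")[[1]][1]
  pairs <- NULL
  for (i in seq_along(keep_lab)) for (j in seq_along(keep_lab)) {
    if (i < j && first_of(keep_lab[i]) == first_of(keep_lab[j]))
      pairs <- rbind(pairs, c(keep_lab[i], keep_lab[j]))
  }
  for (b in names(conn)) {
    gm <- subject_global_means(conn[[b]])
    for (lab in keep_lab) {
      v <- gm[traj == lab]
      summaries <- rbind(summaries, data.frame(
        band = b, trajectory = lab, mean = mean(v), n = length(v)))
    }
    if (!is.null(pairs)) for (k in seq_len(nrow(pairs))) {
      xa <- gm[traj == pairs[k, 1]]; xb <- gm[traj == pairs[k, 2]]
      tests <- rbind(tests,
        data.frame(band = b, group_a = pairs[k, 1], group_b = pairs[k, 2],
                   direction = "A>B", p = rank_sum_p(xa, xb),
                   effect = effect_size(xa, xb)),
        data.frame(band = b, group_a = pairs[k, 1], group_b = pairs[k, 2],
                   direction = "B>A", p = rank_sum_p(xb, xa),
                   effect = effect_size(xb, xa)))
    }
  }
  if (!is.null(tests)) {
    tests$p_adj <- NA_real_
    for (d in unique(tests$direction)) {
      for (g in unique(paste(tests$group_a, tests$group_b))) {
        idx <- tests$direction == d & paste(tests$group_a, tests$group_b) == g
        tests$p_adj[idx] <- p.adjust(tests$p[idx], method = "BH")
      }
    }
    tests$significant <- tests$p_adj <= alpha
  }
  list(summaries = summaries, tests = tests, dropped = dropped)
}
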