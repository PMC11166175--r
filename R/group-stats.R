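#' Kruskal-Wallis test on group counts
#'
#' Rank-based H with tie correction and a p-value from the chi-square
#' approximation on (groups - 1) degrees of freedom (via
#' [stats::kruskal.test()]). For small samples (total N <= 8 by default) an
#' exact p-value is also computed by exhaustive enumeration of every
#' assignment of the pooled observations to the group sizes, counting
#' assignments with H at least as large as observed.
#'
#' @param samples List of >= 2 non-empty numeric vectors, one per group.
#' @param exact_max Largest total N for which the exact permutation p is
#'   computed (default 8).
#' @return List with `H`, `df`, `p_value` (chi-square), `p_exact` (NA when
#'   not computed) and group sizes `n`.
#' @export
kruskal_wallis <- function(samples, exact_max = 8L) {
  assert_that(is.list(samples) && length(samples) >= 2,
              "samples must be a list of >= 2 groups")
  sizes <- lengths(samples)
  assert_that(all(sizes >= 1), "every group must be non-empty")
  N <- sum(sizes)
  assert_that(N >= 3, "need at least 3 observations in total")
  values <- unlist(samples, use.names = FALSE)
  g <- factor(rep(seq_along(samples), sizes))

  if (length(unique(values)) == 1) {
    return(list(H = 0, df = length(samples) - 1L, p_value = 1,
                p_exact = if (N <= exact_max) 1 else NA_real_, n = sizes))
  }
  kt <- stats::kruskal.test(values, g)
  H <- unname(kt$statistic)

  p_exact <- NA_real_
  if (N <= exact_max) {
    ranks <- rank(values)
    perms <- group_assignments(N, sizes)
    Hs <- vapply(perms, function(idx) kw_H_from_ranks(ranks, idx, sizes),
                 numeric(1))
    p_exact <- mean(Hs >= H - 1e-12)
  }
  list(H = H, df = length(samples) - 1L, p_value = unname(kt$p.value),
       p_exact = p_exact, n = sizes)
}

#' H from pre-ranked pooled data for a given assignment (tie-corrected).
#' `idx` is a permutation of 1..N; the first n1 entries go to group 1, etc.
#' @noRd
kw_H_from_ranks <- function(ranks, idx, sizes) {
  N <- length(ranks)
  offs <- c(0, cumsum(sizes))
  s <- 0
  for (g in seq_along(sizes)) {
    rg <- ranks[idx[(offs[g] + 1):offs[g + 1]]]
    s <- s + sum(rg)^2 / sizes[g]
  }
  H <- 12 / (N * (N + 1)) * s - 3 * (N + 1)
  tab <- table(ranks)
  corr <- 1 - sum(tab^3 - tab) / (N^3 - N)
  H / corr
}

#' Enumerate all assignments of N items to ordered groups of given sizes
#' @noRd
group_assignments <- function(N, sizes) {
  recurse <- function(avail, sizes) {
    if (length(sizes) == 1) return(list(avail))
    picks <- utils::combn(avail, sizes[1], simplify = FALSE)
    out <- list()
    for (p in picks) {
      rest <- recurse(setdiff(avail, p), sizes[-1])
      out <- c(out, lapply(rest, function(r) c(p, r)))
    }
    out
  }
  recurse(seq_len(N), sizes)
}

#' Descriptive FDR critical value
#'
#' The critical p-value `i * q / (V * c_V)` reported alongside a ranked
#' volume-of-activation table, where `i` is the number of nominally
#' significant regions (p < 0.05), out of `V` regions tested at filter level
#' `q`. Returned at full precision with a 3-decimal rounded copy attached as
#' attribute `"rounded"`.
#'
#' @param i Count of nominally significant regions (0 <= i <= V).
#' @param params An [fdr_params()].
#' @return Numeric critical value; `attr(, "rounded")` holds `round(x, 3)`.
#' @export
fdr_critical_value <- function(i, params = fdr_params()) {
  stopifnot(inherits(params, "fdr_params"))
  assert_that(i >= 0 && i <= params$V, "i must lie in [0, V]")
  x <- i * params$q / (params$V * params$c_V)
  attr(x, "rounded") <- round(x, 3)
  x
}

#' Ranked volume-of-activation group comparison table
#'
#' Reproduces the published tables' machinery: for every atlas region, the
#' activated-voxel counts (one arm, positive or negative BOLD) are compared
#' across the selected groups with a Kruskal-Wallis test; regions with
#' p < `alpha` are retained, ranked ascending by p-value, with per-group
#' medians (the lower middle value for even n, matching integer medians), a
#' direction symbol, and the descriptive FDR critical value for the number
#' of retained rows.
#'
#' @param counts Data frame with columns `subject_id`, `region_id`,
#'   `positive_count`, `negative_count` (e.g. stacked
#'   [classify_and_count()] outputs).
#' @param design A [group_design()] assigning subjects to groups.
#' @param arm "positive" or "negative" BOLD.
#' @param compare Character vector of >= 2 group labels to compare (default:
#'   all groups present, in Veh/LSD10/LSD100 order).
#' @param alpha Nominal significance cut for a row to be retained.
#' @param fdr An [fdr_params()] (V defaults to the number of regions).
#' @param region_names Optional named vector region_id -> name.
#' @return A `voa_table`: data frame of retained rows plus header metadata
#'   (`arm`, `groups`, `V`, `q`, `fdr_critical`, `fdr_critical_rounded`,
#'   `n_regions_tested`).
#' @export
build_voa_table <- function(counts, design, arm = c("negative", "positive"),
                            compare = NULL, alpha = 0.05, fdr = NULL,
                            region_names = NULL) {
  arm <- match.arg(arm)
  stopifnot(inherits(design, "group_design"))
  required <- c("subject_id", "region_id", "positive_count", "negative_count")
  assert_that(all(required %in% names(counts)),
              "counts needs columns %s", paste(required, collapse = ", "))
  subj <- design$subjects
  counts$group <- subj$group[match(counts$subject_id, subj$subject_id)]
  assert_that(!anyNA(counts$group), "counts contain unknown subjects")

  groups_present <- intersect(c("Veh", "LSD10", "LSD100"),
                              unique(counts$group))
  compare <- compare %||% groups_present
  assert_that(length(compare) >= 2, "fewer than 2 groups selected")
  assert_that(all(compare %in% groups_present),
              "selected groups absent from the counts")
  counts <- counts[counts$group %in% compare, ]

  regions <- sort(unique(counts$region_id))
  # every subject must report every region
  per_subj <- table(counts$subject_id)
  assert_that(length(unique(per_subj)) == 1 &&
                unique(per_subj) == length(regions),
              "every subject must have counts for every region")
  value_col <- paste0(arm, "_count")
  fdr <- fdr %||% fdr_params(V = length(regions))

  med_low <- function(v) sort(v)[floor((length(v) + 1) / 2)]
  rows <- lapply(regions, function(rid) {
    sub <- counts[counts$region_id == rid, ]
    samples <- lapply(compare, function(g) sub[[value_col]][sub$group == g])
    kw <- kruskal_wallis(samples, exact_max = 0L)
    meds <- vapply(samples, med_low, numeric(1))
    data.frame(region_id = rid, t(stats::setNames(meds,
                                                  paste0("med_", compare))),
               H = kw$H, p_value = kw$p_value)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(region_names)) {
    tab$name <- unname(region_names[as.character(tab$region_id)])
  }
  keep <- tab[tab$p_value < alpha, , drop = FALSE]
  keep <- keep[order(keep$p_value, keep$region_id), , drop = FALSE]
  if (nrow(keep)) {
    keep$rank <- seq_len(nrow(keep))
    m1 <- keep[[paste0("med_", compare[1])]]
    m2 <- keep[[paste0("med_", compare[2])]]
    keep$direction <- ifelse(m1 > m2, ">", ifelse(m1 < m2, "<", "="))
  } else {
    keep$rank <- integer(0)
    keep$direction <- character(0)
  }
  rownames(keep) <- NULL
  crit <- fdr_critical_value(nrow(keep), fdr)
  structure(list(table = keep, arm = arm, groups = compare,
                 V = fdr$V, q = fdr$q, alpha = alpha,
                 fdr_critical = as.numeric(crit),
                 fdr_critical_rounded = attr(crit, "rounded"),
                 n_regions_tested = length(regions)),
            class = "voa_table")
}

#' @export
print.voa_table <- function(x, digits = 3, ...) {
  arm_lab <- paste0(toupper(substring(x$arm, 1, 1)), substring(x$arm, 2))
  cat(sprintf("%s volume of activation: %s\n",
              arm_lab, paste(x$groups, collapse = " vs ")))
  cat(sprintf("  %d/%d regions significant at alpha = %g (FDR P = %.3f)\n",
              nrow(x$table), x$n_regions_tested, x$alpha,
              x$fdr_critical_rounded))
  if (nrow(x$table)) print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}
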