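#' Normalize a metabolite table for enrichment analysis
#'
#' Urine: each metabolite is divided by the same-sample creatinine
#' concentration (reported as mmol/mol creatinine, i.e. x 1000), the
#' creatinine column is dropped, then every metabolite is autoscaled
#' (mean-centered, divided by its standard deviation). Plasma and CSF
#' (absolute mmol/L): autoscaling only. Zero-variance metabolites are
#' dropped with a warning.
#'
#' @param table Numeric matrix, samples x metabolites (named columns); for
#'   urine it must contain a `creatinine` column with positive values.
#' @param biofluid One of `"urine"`, `"plasma"`, `"csf"`.
#' @return Scaled numeric matrix (column means 0, sds 1).
#' @export
normalize_for_qea <- function(table, biofluid) {
  biofluid <- match_biofluid(biofluid)
  x <- as.matrix(table)
  if (is.null(colnames(x))) stop("table needs metabolite column names", call. = FALSE)
  if (any(x < 0, na.rm = TRUE)) stop("concentrations must be >= 0", call. = FALSE)
  if (biofluid == "urine") {
    ci <- match("creatinine", tolower(colnames(x)))
    if (is.na(ci)) stop("urine table has no creatinine column", call. = FALSE)
    crea <- x[, ci]
    bad <- which(!is.finite(crea) | crea <= 0)
    if (length(bad) > 0L) {
      ids <- rownames(x)[bad] %||% as.character(bad)
      stop("creatinine missing or non-positive for sample(s): ",
           paste(ids, collapse = ", "), call. = FALSE)
    }
    x <- x[, -ci, drop = FALSE] / crea * 1000  # mmol/mol creatinine
  }
  sds <- apply(x, 2L, stats::sd)
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop)) {
    warning("dropping zero-variance metabolite(s): ",
            paste(colnames(x)[drop], collapse = ", "), call. = FALSE)
    x <- x[, !drop, drop = FALSE]
    sds <- sds[!drop]
  }
  if (ncol(x) == 0L) stop("no metabolites left after filtering", call. = FALSE)
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Global test Q-statistic for one metabolite set
#'
#' Linear-model global test of association between a set of (scaled)
#' metabolite columns X and a two-level outcome. With z the centered
#' outcome indicator, m the member count, and n the sample count:
#' \deqn{Q = z' X X' z / (m \, z'z/n).}
#' The p-value comes from outcome-label permutation:
#' p = (1 + #\{Q_perm >= Q_obs\}) / (1 + n_perm).
#'
#' @param set_matrix Numeric matrix, samples x member metabolites.
#' @param outcome Two-level factor/vector aligned to rows.
#' @param n_perm Number of permutations (default 1999).
#' @param seed Optional integer seed for the permutations.
#' @return List with `Q`, `p_value`, and `null_mean` (mean permutation Q,
#'   used for enrichment ratios).
#' @export
globaltest_q <- function(set_matrix, outcome, n_perm = 1999L, seed = NULL) {
  x <- as.matrix(set_matrix)
  outcome <- as.character(outcome)
  stopifnot(nrow(x) == length(outcome), ncol(x) >= 1L)
  lev <- sort(unique(outcome))
  if (length(lev) != 2L) stop("outcome must have exactly 2 levels", call. = FALSE)
  if (any(table(outcome) < 2L)) stop("need >= 2 samples per outcome level", call. = FALSE)
  z <- ifelse(outcome == lev[2L], 1, -1)
  z <- z - mean(z)
  n <- length(z); m <- ncol(x)
  qstat <- function(zv) {
    xz <- crossprod(x, zv)
    sum(xz^2) / (m * sum(zv^2) / n)
  }
  q_obs <- qstat(z)
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
  }
  q_null <- vapply(seq_len(n_perm), function(i) qstat(sample(z)), numeric(1L))
  list(Q = q_obs,
       p_value = (1 + sum(q_null >= q_obs - 1e-12)) / (1 + n_perm),
       null_mean = mean(q_null))
}

#' Quantitative enrichment analysis over a pathway library
#'
#' Normalizes the concentration table for the biofluid, then for every
#' pathway with at least `min_set_size` measured members computes the
#' global test Q-statistic, its permutation p-value, and the enrichment
#' ratio Q_observed / mean(Q under the permutation null). Metabolite names
#' are matched case-insensitively after stripping punctuation and spaces.
#' The contrast is two-class; rows with other labels are dropped.
#'
#' @param table Numeric matrix, samples x metabolites.
#' @param labels Class labels aligned to rows.
#' @param library Named list `pathway -> character vector of members` (see
#'   [read_gmt()]).
#' @param biofluid Passed to [normalize_for_qea()].
#' @param contrast Length-2 character: the two class labels to compare
#'   (default the two alphabetically first labels present).
#' @param n_perm,seed Passed to [globaltest_q()].
#' @param min_set_size Minimum measured members per tested set (default 2).
#' @return Data frame sorted by p-value: `pathway`, `n_members_measured`,
#'   `Q`, `p_value`, `enrichment_ratio`, `members` (comma-separated).
#' @export
run_qea <- function(table, labels, library, biofluid,
                    contrast = NULL, n_perm = 1999L, seed = 1L,
                    min_set_size = 2L) {
  x <- as.matrix(table)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  if (is.null(contrast)) contrast <- sort(unique(labels))[1:2]
  stopifnot(length(contrast) == 2L, all(contrast %in% labels))
  keep <- labels %in% contrast
  scaled <- normalize_for_qea(x[keep, , drop = FALSE], biofluid)
  outcome <- labels[keep]
  key <- canonical_name(colnames(scaled))
  results <- list()
  for (pw in names(library)) {
    member_key <- canonical_name(library[[pw]])
    hit <- which(key %in% member_key)
    if (length(hit) < min_set_size) {
      message("skipping set '", pw, "' (", length(hit), " measured member(s))")
      next
    }
    gt <- globaltest_q(scaled[, hit, drop = FALSE], outcome,
                       n_perm = n_perm,
                       seed = seed + length(results))
    results[[pw]] <- data.frame(
      pathway = pw, n_members_measured = length(hit),
      Q = gt$Q, p_value = gt$p_value,
      enrichment_ratio = gt$Q / gt$null_mean,
      members = paste(colnames(scaled)[hit], collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(results) == 0L) {
    stop("no pathway has >= ", min_set_size, " measured members", call. = FALSE)
  }
  out <- do.call(rbind, results)
  rownames(out) <- NULL
  out[order(out$p_value, -out$Q), , drop = FALSE]
}

canonical_name <- function(x) {
  tolower(gsub("[^a-z0-9]", "", tolower(x)))
}

#' Select the top enriched sets for a summary plot
#'
#' @param qea Data frame from [run_qea()].
#' @param n Number of sets to keep (default 25, the usual dot-plot size).
#' @return The first `n` rows by ascending p-value.
#' @export
top_enriched <- function(qea, n = 25L) {
  utils::head(qea[order(qea$p_value, -qea$Q), , drop = FALSE], n)
}

#' Three-way Venn region counts for enriched pathway sets
#'
#' @param per_biofluid Named list of exactly three character vectors of
#'   pathway names (e.g. significant sets per biofluid).
#' @return List with `counts` (named 7-region integer vector, names like
#'   `"urine_only"`, `"urine_plasma"`, `"all_three"`) and `members`
#'   (the names per region).
#' @export
venn_overlap <- function(per_biofluid) {
  stopifnot(is.list(per_biofluid), length(per_biofluid) == 3L)
  nm <- names(per_biofluid) %||% c("A", "B", "C")
  a <- unique(per_biofluid[[1L]]); b <- unique(per_biofluid[[2L]])
  cc <- unique(per_biofluid[[3L]])
  members <- list()
  members[[paste0(nm[1L], "_only")]] <- setdiff(a, union(b, cc))
  members[[paste0(nm[2L], "_only")]] <- setdiff(b, union(a, cc))
  members[[paste0(nm[3L], "_only")]] <- setdiff(cc, union(a, b))
  members[[paste(nm[1L], nm[2L], sep = "_")]] <- setdiff(intersect(a, b), cc)
  members[[paste(nm[1L], nm[3L], sep = "_")]] <- setdiff(intersect(a, cc), b)
  members[[paste(nm[2L], nm[3L], sep = "_")]] <- setdiff(intersect(b, cc), a)
  members[["all_three"]] <- Reduce(intersect, list(a, b, cc))
  list(counts = vapply(members, length, integer(1L)), members = members)
}

#' Metabolite ordering for a concentration heatmap
#'
#' Pairwise Euclidean distances between metabolite columns of the scaled
#' matrix, with the leaf order of average-linkage hierarchical clustering.
#'
#' @param scaled Numeric matrix, samples x metabolites (>= 2 columns).
#' @return List with `order` (metabolite names in leaf order), `dist`
#'   (the `dist` object), and `hclust` (the tree).
#' @export
heatmap_order <- function(scaled) {
  x <- as.matrix(scaled)
  stopifnot(ncol(x) >= 2L)
  d <- stats::dist(t(x), method = "euclidean")
  hc <- stats::hclust(d, method = "average")
  list(order = (colnames(x) %||% as.character(seq_len(ncol(x))))[hc$order],
       dist = d, hclust = hc)
}
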