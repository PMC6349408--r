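#' Genotype dosage container
#'
#' Variants x samples dosage matrix (0-2, expected alt-allele count) with
#' variant coordinates. Upstream filtering (bi-allelic variants, MAF > 0.05)
#' is assumed to have been applied already; dosages outside `[0, 2]` are
#' rejected.
#'
#' @param dosage numeric matrix, variants x samples, with row and column
#'   names.
#' @param chrom,pos vectors of variant coordinates (one per row).
#' @param ref,alt optional allele annotations.
#' @return A `txe_genotypes` object.
#' @export
genotype_matrix <- function(dosage, chrom, pos, ref = NULL, alt = NULL) {
  stopifnot(is.matrix(dosage), !is.null(rownames(dosage)),
            !is.null(colnames(dosage)),
            length(chrom) == nrow(dosage), length(pos) == nrow(dosage))
  if (any(dosage < 0 | dosage > 2)) stop("dosages must lie in [0, 2]")
  if (anyDuplicated(rownames(dosage))) stop("duplicate variant ids")
  structure(
    list(dosage = dosage, chrom = as.character(chrom), pos = as.integer(pos),
         ref = ref, alt = alt),
    class = "txe_genotypes"
  )
}

# Variant rows within +/- window of an anchor position.
variants_in_window <- function(geno, anchor_chrom, anchor_pos, window) {
  which(geno$chrom == anchor_chrom & abs(geno$pos - anchor_pos) <= window)
}

# Residualize columns of m on covariates (with intercept); cov may be NULL.
residualize <- function(m, covariates) {
  x <- cbind(Intercept = rep(1, nrow(m)), covariates)
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) stop("covariate matrix is rank deficient")
  m - x %*% qr.coef(qr_x, m)
}

#' Nominal cis association scan
#'
#' Ordinary least squares of a feature phenotype on each variant's dosage
#' within a cis window around the feature's anchor (its 5'-most genomic
#' coordinate), adjusting for covariates, with a two-sided t-test per
#' variant. Samples with a missing phenotype value are dropped pairwise.
#'
#' @param pheno named numeric vector (sample id -> phenotype).
#' @param geno a [genotype_matrix()].
#' @param covariates optional samples x k matrix (rownames = sample ids),
#'   e.g. the leading phenotype principal components from [phenotype_pcs()].
#' @param anchor_chrom,anchor_pos anchor coordinate of the feature.
#' @param window cis window half-width in bp (default 500000).
#' @return data.frame with `variant_id`, `beta`, `se`, `p_nominal`.
#' @export
nominal_scan <- function(pheno, geno, covariates = NULL,
                         anchor_chrom = geno$chrom[1L], anchor_pos = NULL,
                         window = 500000L) {
  rows <- if (is.null(anchor_pos)) seq_along(geno$chrom) else
    variants_in_window(geno, anchor_chrom, anchor_pos, window)
  if (length(rows) == 0L) {
    return(data.frame(variant_id = character(), beta = numeric(),
                      se = numeric(), p_nominal = numeric()))
  }
  samples <- intersect(names(pheno)[!is.na(pheno)], colnames(geno$dosage))
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  if (length(samples) < k + 3L) {
    stop("fewer samples (", length(samples), ") than covariates + 3")
  }
  y <- pheno[samples]
  g <- t(geno$dosage[rows, samples, drop = FALSE]) # samples x variants
  cov <- if (is.null(covariates)) NULL else
    as.matrix(covariates)[samples, , drop = FALSE]
  ym <- residualize(cbind(y), cov)
  gm <- residualize(g, cov)
  gss <- colSums(gm^2)
  if (any(gss < 1e-12)) {
    stop("dosage collinear with covariates (rank deficiency) for variant(s): ",
         paste(colnames(g)[gss < 1e-12], collapse = ", "))
  }
  df <- length(samples) - 2L - k
  beta <- as.numeric(crossprod(gm, ym)) / gss
  rss <- colSums((ym[, 1L] - sweep(gm, 2L, beta, `*`))^2)
  se <- sqrt(rss / df / gss)
  tstat <- beta / se
  data.frame(
    variant_id = rownames(geno$dosage)[rows],
    beta = beta, se = se,
    p_nominal = 2 * stats::pt(-abs(tstat), df = df),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Leading principal components of a phenotype matrix
#'
#' @param pheno features x samples matrix (`NA`-free rows are used).
#' @param n number of components (default 6).
#' @return samples x n matrix of scores.
#' @export
phenotype_pcs <- function(pheno, n = 6L) {
  ok <- stats::complete.cases(pheno)
  p <- stats::prcomp(t(pheno[ok, , drop = FALSE]), center = TRUE, scale. = FALSE)
  p$x[, seq_len(min(n, ncol(p$x))), drop = FALSE]
}

#' Permutation pass with group-best correction
#'
#' Computes, for one scope (all features of a gene and event type, pooling
#' the two construction groups), the minimal nominal p-value over all
#' (variant, feature) pairs in a cis window, and its empirical p-value under
#' permutations of sample labels. Sample labels are shuffled jointly across
#' the scope's features, preserving inter-feature correlation, so the minimum
#' over features is corrected for the number of alternative events tested.
#' The empirical p-value uses the direct estimator with pseudocount,
#' `(1 + #{permuted min-p <= observed}) / (n_perm + 1)`, and therefore never
#' falls below `1 / (n_perm + 1)`.
#'
#' @param pheno_block features x samples matrix (one scope). Samples with a
#'   missing value in any feature of the scope are dropped.
#' @param geno a [genotype_matrix()].
#' @param covariates optional samples x k covariate matrix; phenotypes and
#'   dosages are residualized once and residuals are permuted.
#' @param n_perm number of permutations (default 10000; < 100 warns).
#' @param anchor_chrom,anchor_pos scope anchor; `NULL` anchor uses all
#'   variants.
#' @param window cis window half-width in bp (default 100000).
#' @return List with `p_empirical`, `lead_variant`, `lead_feature`,
#'   `lead_beta`, `p_nominal_min`, `n_samples`, `n_variants`, or `NULL` when
#'   no variant falls in the window (a message is emitted).
#' @export
permutation_pass <- function(pheno_block, geno, covariates = NULL,
                             n_perm = 10000L, anchor_chrom = geno$chrom[1L],
                             anchor_pos = NULL, window = 100000L) {
  stopifnot(is.matrix(pheno_block))
  if (n_perm < 100L) warning("n_perm < 100 gives a very coarse empirical p")
  rows <- if (is.null(anchor_pos)) seq_along(geno$chrom) else
    variants_in_window(geno, anchor_chrom, anchor_pos, window)
  if (length(rows) == 0L) {
    message("scope has no variants within the cis window; skipped")
    return(NULL)
  }
  keep_feat <- apply(pheno_block, 1L, function(x) !all(is.na(x)))
  pheno_block <- pheno_block[keep_feat, , drop = FALSE]
  samples <- colnames(pheno_block)[stats::complete.cases(t(pheno_block))]
  samples <- intersect(samples, colnames(geno$dosage))
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  n <- length(samples)
  if (n < k + 3L) stop("fewer samples than covariates + 3")
  df <- n - 2L - k

  y <- t(pheno_block[, samples, drop = FALSE]) # samples x features
  g <- t(geno$dosage[rows, samples, drop = FALSE]) # samples x variants
  cov <- if (is.null(covariates)) NULL else
    as.matrix(covariates)[samples, , drop = FALSE]
  ym <- residualize(y, cov)
  gm <- residualize(g, cov)
  keep_v <- colSums(gm^2) > 1e-12
  if (!any(keep_v)) {
    message("all scope variants constant after covariate adjustment; skipped")
    return(NULL)
  }
  gm <- gm[, keep_v, drop = FALSE]
  rows <- rows[keep_v]
  keep_f <- apply(ym, 2L, function(x) stats::sd(x) > 0)
  if (!any(keep_f)) {
    message("all scope features constant; skipped")
    return(NULL)
  }
  ym <- ym[, keep_f, drop = FALSE]

  gn <- sweep(gm, 2L, sqrt(colSums(gm^2)), `/`)
  yn <- sweep(ym, 2L, sqrt(colSums(ym^2)), `/`)
  r_obs <- crossprod(gn, yn) # variants x features
  obs_max <- max(r_obs^2)

  # one permutation of sample labels applied jointly to all features
  perm_mat <- vapply(seq_len(n_perm), function(b) sample.int(n), integer(n))
  perm_max <- rep(0, n_perm)
  for (f in seq_len(ncol(yn))) {
    yp <- matrix(yn[perm_mat, f], nrow = n) # n x n_perm
    r2p <- crossprod(gn, yp)^2 # variants x n_perm
    best_row <- max.col(t(r2p), ties.method = "first")
    perm_max <- pmax(perm_max, r2p[cbind(best_row, seq_len(n_perm))])
  }
  p_emp <- (1 + sum(perm_max >= obs_max)) / (n_perm + 1)

  # lead pair: maximal r^2 <=> minimal nominal p (common df); ties break to
  # smallest variant position, then lexicographic variant id
  r2 <- r_obs^2
  best <- which(r2 == max(r2), arr.ind = TRUE)
  ord <- order(geno$pos[rows][best[, 1L]],
               rownames(geno$dosage)[rows][best[, 1L]])
  vi <- best[ord[1L], 1L]
  fi <- best[ord[1L], 2L]
  r_lead <- r_obs[vi, fi]
  t_lead <- r_lead * sqrt(df / max(1 - r_lead^2, 1e-300))
  beta_lead <- r_lead * sqrt(colSums(ym^2)[fi] / colSums(gm^2)[vi])
  list(
    p_empirical = p_emp,
    lead_variant = rownames(geno$dosage)[rows][vi],
    lead_feature = colnames(ym)[fi],
    lead_beta = beta_lead,
    p_nominal_min = 2 * stats::pt(-abs(t_lead), df = df),
    n_samples = n,
    n_variants = length(rows)
  )
}

#' Benjamini-Hochberg FDR
#'
#' Step-up FDR adjustment (wrapper over [stats::p.adjust()]) with input
#' validation for permutation p-values.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  stopifnot(is.numeric(p))
  if (length(p) == 0L) return(numeric())
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Linkage disequilibrium r-squared
#'
#' Squared Pearson correlation between two dosage vectors over shared
#' samples; invariant to allele flipping (`b = 2 - a` gives 1).
#'
#' @param a,b numeric dosage vectors of equal length.
#' @return r^2 in `[0, 1]`, or `NA` when either vector is constant.
#' @export
ld_r2 <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(NA_real_)
  stats::cor(a[ok], b[ok])^2
}

#' Cross-method replication fraction
#'
#' Fraction of the query method's significant lead variant-gene pairs whose
#' reference-method lead for the same gene is in high LD with the query
#' lead. Genes with no reference lead count as non-replicated (conservative
#' reading; set `drop_missing = TRUE` to restrict the denominator to shared
#' genes). The measure is asymmetric between methods by construction.
#'
#' @param query data.frame with `gene_id`, `variant_id` (query leads,
#'   typically pre-filtered to FDR < 0.01).
#' @param reference data.frame with `gene_id`, `variant_id`.
#' @param geno a [genotype_matrix()] containing both lead variants.
#' @param r2_threshold LD threshold (default 0.8, strict `>`).
#' @param drop_missing see above.
#' @return Replication fraction in `[0, 1]`, `NA` for an empty query set.
#' @export
replication_fraction <- function(query, reference, geno, r2_threshold = 0.8,
                                 drop_missing = FALSE) {
  if (nrow(query) == 0L) return(NA_real_)
  hit <- logical(nrow(query))
  found <- logical(nrow(query))
  for (i in seq_len(nrow(query))) {
    j <- which(reference$gene_id == query$gene_id[i])
    if (length(j) == 0L) next
    found[i] <- TRUE
    qv <- query$variant_id[i]
    rv <- reference$variant_id[j[1L]]
    if (!qv %in% rownames(geno$dosage) || !rv %in% rownames(geno$dosage)) {
      stop("lead variant missing from genotype matrix: ",
           paste(setdiff(c(qv, rv), rownames(geno$dosage)), collapse = ", "))
    }
    r2 <- ld_r2(geno$dosage[qv, ], geno$dosage[rv, ])
    hit[i] <- !is.na(r2) && r2 > r2_threshold
  }
  if (drop_missing) {
    if (!any(found)) return(NA_real_)
    mean(hit[found])
  } else {
    mean(hit)
  }
}
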