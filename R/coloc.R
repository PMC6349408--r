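#' Filter colocalisation results
#'
#' Applies the standard stringency rules to a table of precomputed
#' colocalisation posterior probabilities (PP0-PP4 from the enumeration of
#' causal-variant configurations; PP3 = two distinct causal variants, PP4 =
#' one shared causal variant). A record is kept iff all of:
#'
#' * `PP3 + PP4 >= 0.8` (enough power to distinguish the two models),
#' * `PP4 / (PP3 + PP4) > 0.9` (shared-variant model strongly preferred),
#' * the region does not overlap the MHC (GRCh38 chr6:28,510,120-33,480,577,
#'   excluded for its complicated LD), and
#' * the minimal GWAS p-value in the region is `< 1e-6`.
#'
#' Record order is preserved, and the filter is idempotent.
#'
#' @param records data.frame with columns `PP0`..`PP4`, `chrom`, `start`,
#'   `end` (region, 1-based inclusive) and `gwas_min_p`. PP columns must sum
#'   to 1 within `pp_tol` per row.
#' @param gwas_p_threshold minimal-GWAS-p rule (default `1e-6`).
#' @param pp_tol tolerance on the PP sum check (default `1e-6`).
#' @return The retained rows of `records`.
#' @export
filter_colocalisations <- function(records, gwas_p_threshold = 1e-6,
                                   pp_tol = 1e-6) {
  need <- c(paste0("PP", 0:4), "chrom", "start", "end", "gwas_min_p")
  missing_cols <- setdiff(need, colnames(records))
  if (length(missing_cols)) {
    stop("colocalisation table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) == 0L) return(records)
  pp_sum <- rowSums(records[, paste0("PP", 0:4)])
  if (any(abs(pp_sum - 1) > pp_tol)) {
    stop("PP0..PP4 do not sum to 1 for row(s): ",
         paste(which(abs(pp_sum - 1) > pp_tol), collapse = ", "))
  }
  p34 <- records$PP3 + records$PP4
  ratio <- ifelse(p34 > 0, records$PP4 / p34, 0)
  mhc <- mhc_region()
  in_mhc <- normalize_chrom(records$chrom) == mhc$chrom &
    records$start <= mhc$end & records$end >= mhc$start
  keep <- p34 >= 0.8 & ratio > 0.9 & !in_mhc &
    records$gwas_min_p < gwas_p_threshold
  records[keep, , drop = FALSE]
}

mhc_region <- function() list(chrom = "6", start = 28510120L, end = 33480577L)

normalize_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

#' Candidate regions for colocalisation testing
#'
#' Selects the QTL lead variants worth testing against a GWAS: a lead
#' qualifies when at least one GWAS variant with nominal p below
#' `gwas_p_threshold` lies within `max_distance` of it, and the candidate
#' region is a `region_size` window centered on the lead.
#'
#' @param leads data.frame with `gene_id`, `variant_id`, `chrom`, `pos`.
#' @param gwas data.frame with `chrom`, `pos`, `p`.
#' @param gwas_p_threshold GWAS hit threshold (default `1e-5`).
#' @param max_distance lead-to-hit distance limit in bp (default 100000).
#' @param region_size total width of the candidate region (default 400000).
#' @return The qualifying rows of `leads` with `region_start` and
#'   `region_end` columns appended.
#' @export
coloc_candidate_regions <- function(leads, gwas, gwas_p_threshold = 1e-5,
                                    max_distance = 100000L,
                                    region_size = 400000L) {
  stopifnot(all(c("gene_id", "variant_id", "chrom", "pos") %in% colnames(leads)),
            all(c("chrom", "pos", "p") %in% colnames(gwas)))
  hits <- gwas[gwas$p < gwas_p_threshold, , drop = FALSE]
  qual <- vapply(seq_len(nrow(leads)), function(i) {
    same <- normalize_chrom(hits$chrom) == normalize_chrom(leads$chrom[i])
    any(same & abs(hits$pos - leads$pos[i]) <= max_distance)
  }, logical(1))
  out <- leads[qual, , drop = FALSE]
  half <- as.integer(region_size / 2)
  out$region_start <- out$pos - half
  out$region_end <- out$pos + half
  out
}
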