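## Cancer cell fraction computation: VAF -> CCF corrected for purity, local
## copy number and mutation multiplicity, with binomial variance propagation.

#' Estimate mutation multiplicity from VAF, purity and copy number
#'
#' Nearest-integer estimate of the number of mutated allele copies per tumor
#' cell: \eqn{\hat m = round(VAF (\rho CN_t + (1-\rho) 2) / \rho)}, clamped to
#' \code{[1, cn_total]}. Ties at .5 round half-up for reproducibility across
#' platforms.
#'
#' @param vaf Variant allele fraction in \code{[0, 1]}.
#' @param purity Tumor purity in (0, 1].
#' @param cn_total Total copy number at the locus (integer >= 1).
#' @return Integer multiplicity in \code{[1, cn_total]}.
#' @examples
#' estimate_multiplicity(0.4, 0.8, 4)  # 2
#' @export
estimate_multiplicity <- function(vaf, purity, cn_total) {
  if (any(purity <= 0) || any(purity > 1))
    stop("purity must be in (0, 1]")
  if (any(cn_total < 1)) stop("cn_total must be >= 1 (invalid segment)")
  m_raw <- vaf * (purity * cn_total + (1 - purity) * 2) / purity
  m <- floor(m_raw + 0.5)  # round half-up
  as.integer(pmin(pmax(m, 1), cn_total))
}

#' Compute a purity/copy-number-corrected cancer cell fraction
#'
#' \deqn{CCF_{raw} = VAF (\rho CN_t + (1-\rho) 2) / (\rho m)}
#' with \eqn{\rho} the tumor purity, \eqn{CN_t} the local total copy number
#' and \eqn{m} the mutation multiplicity. The reported \code{ccf} is clamped
#' at 1; \code{raw_ccf} is preserved for QC. The variance is first-order
#' propagation of the binomial VAF variance
#' \eqn{VAF(1-VAF)/total\_reads} through the linear correction.
#'
#' @param alt_reads,total_reads Variant and total read counts at the site.
#' @param purity Tumor purity in (0, 1].
#' @param cn_total Total copy number at the locus.
#' @param m Multiplicity; \code{"auto"} (default) applies
#'   \code{\link{estimate_multiplicity}}.
#' @return A one-row data frame: \code{vaf}, \code{m}, \code{raw_ccf},
#'   \code{ccf}, \code{variance}, \code{cn_total}, \code{purity}. Vectorized
#'   over read counts and per-site parameters.
#' @examples
#' compute_ccf(75, 150, purity = 1, cn_total = 2, m = 1)
#' @export
compute_ccf <- function(alt_reads, total_reads, purity, cn_total, m = "auto") {
  if (any(total_reads == 0))
    stop("total_reads = 0: uncovered site; decide missing vs zero upstream")
  if (any(alt_reads < 0 | alt_reads > total_reads))
    stop("alt_reads must be in [0, total_reads]")
  if (any(purity <= 0) || any(purity > 1)) stop("purity must be in (0, 1]")
  if (any(cn_total < 1)) stop("cn_total must be >= 1")
  vaf <- alt_reads / total_reads
  if (identical(m, "auto")) m <- estimate_multiplicity(vaf, purity, cn_total)
  scale <- (purity * cn_total + (1 - purity) * 2) / (purity * m)
  raw <- vaf * scale
  var_vaf <- vaf * (1 - vaf) / total_reads
  data.frame(vaf = vaf, m = as.integer(m), raw_ccf = raw,
             ccf = pmin(raw, 1), variance = scale^2 * var_vaf,
             cn_total = as.integer(cn_total), purity = purity)
}

#' Build a mutation x sample CCF matrix from per-sample call tables
#'
#' Harmonizes mutation keys (chrom, pos, ref, alt) across samples and converts
#' each call to a CCF. A mutation absent in a sample but covered at
#' \code{min_depth} or more reads is assigned CCF 0; a mutation not observed
#' (or observed with zero variant reads below \code{min_depth}) is missing
#' (\code{NA}). Rows missing in every sample are dropped with a message.
#' Row order is deterministic (chrom, then position).
#'
#' @param calls Data frame of mutation calls for two or more samples
#'   (\code{sample_id}, \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{alt_reads}, \code{total_reads}, optional \code{gene}), e.g. from
#'   \code{\link{simulate_biopsy}} or \code{\link{read_mutation_tsv}}.
#' @param purities Named numeric vector of per-sample purities.
#' @param segments Optional SEG-like data frame (\code{sample_id},
#'   \code{chrom}, \code{start}, \code{end}, \code{total_cn}); loci not
#'   covered by a segment are treated as diploid.
#' @param min_depth Minimum coverage to call a site "covered-absent"
#'   (default 20).
#' @param m Multiplicity passed to \code{\link{compute_ccf}}.
#' @return A \code{ccf_matrix} object: list with \code{ccf} (clamped),
#'   \code{raw} (unclamped), \code{variance} matrices (rows = mutation keys,
#'   columns = samples) and an \code{info} data frame (chrom, pos, ref, alt,
#'   gene).
#' @export
ccf_matrix <- function(calls, purities, segments = NULL,
                       min_depth = 20, m = "auto") {
  stopifnot(is.data.frame(calls))
  samples <- unique(calls$sample_id)
  if (length(samples) < 1) stop("no samples in call table")
  missing_p <- setdiff(samples, names(purities))
  if (length(missing_p))
    stop("no purity for sample(s): ", paste(missing_p, collapse = ", "))
  key <- with(calls, paste(chrom, pos, ref, alt, sep = ":"))
  info <- unique(data.frame(key = key, chrom = calls$chrom, pos = calls$pos,
                            ref = calls$ref, alt = calls$alt,
                            gene = if ("gene" %in% names(calls)) calls$gene
                                   else NA_character_,
                            stringsAsFactors = FALSE))
  info <- info[!duplicated(info$key), ]
  info <- info[order(info$chrom, info$pos, info$ref, info$alt), ]
  nmut <- nrow(info)
  mk <- function() matrix(NA_real_, nmut, length(samples),
                          dimnames = list(info$key, samples))
  ccf <- mk(); raw <- mk(); vars <- mk()
  for (s in samples) {
    cs <- calls[calls$sample_id == s, ]
    ks <- with(cs, paste(chrom, pos, ref, alt, sep = ":"))
    idx <- match(ks, info$key)
    seg <- if (!is.null(segments)) segments[segments$sample_id == s, ]
           else NULL
    cn <- cn_at(seg, cs$chrom, cs$pos)
    present <- cs$alt_reads > 0
    covered_absent <- !present & cs$total_reads >= min_depth
    if (any(present)) {
      rec <- compute_ccf(cs$alt_reads[present], cs$total_reads[present],
                         purities[[s]], cn[present], m = m)
      ccf[idx[present], s] <- rec$ccf
      raw[idx[present], s] <- rec$raw_ccf
      vars[idx[present], s] <- rec$variance
    }
    ccf[idx[covered_absent], s] <- 0
    raw[idx[covered_absent], s] <- 0
    vars[idx[covered_absent], s] <- 0
  }
  all_missing <- rowSums(!is.na(ccf)) == 0
  if (any(all_missing)) {
    message(sum(all_missing), " mutation(s) missing in every sample dropped")
    keep <- !all_missing
    ccf <- ccf[keep, , drop = FALSE]
    raw <- raw[keep, , drop = FALSE]
    vars <- vars[keep, , drop = FALSE]
    info <- info[keep, ]
  }
  structure(list(ccf = ccf, raw = raw, variance = vars, info = info),
            class = "ccf_matrix")
}

#' @export
print.ccf_matrix <- function(x, ...) {
  cat("CCF matrix:", nrow(x$ccf), "mutations x", ncol(x$ccf), "samples\n")
  cat("samples:", paste(colnames(x$ccf), collapse = ", "), "\n")
  invisible(x)
}
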