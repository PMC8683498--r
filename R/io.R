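## Flat-file interfaces: mutation TSV and VCF, SEG-like copy-number tables,
## survival TSV and plate CSV. Coordinates are 1-based inclusive throughout
## (VCF/SEG convention).

#' Read / write mutation call tables as TSV
#'
#' Columns: \code{sample_id}, \code{chrom}, \code{pos}, \code{ref},
#' \code{alt}, \code{alt_reads}, \code{total_reads}, \code{gene}.
#'
#' @param calls Mutation call data frame.
#' @param path File path.
#' @return \code{read_mutation_tsv} returns the call data frame;
#'   \code{write_mutation_tsv} returns \code{path} invisibly.
#' @export
write_mutation_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_mutation_tsv
#' @export
read_mutation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "pos", "ref", "alt",
            "alt_reads", "total_reads")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("mutation TSV missing column(s): ", paste(miss, collapse = ", "))
  df$chrom <- as.character(df$chrom)
  df
}

#' Write mutation calls of one sample as a minimal VCF
#'
#' Emits a VCFv4.2 file with \code{AD} (ref,alt depths) and \code{DP} fields
#' for a single sample.
#'
#' @param calls Mutation calls of a single sample.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_mutation_vcf <- function(calls, path) {
  s <- unique(calls$sample_id)
  if (length(s) != 1) stop("write one sample per VCF")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", s)
  ), con)
  ref_reads <- calls$total_reads - calls$alt_reads
  writeLines(paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
                   ".", "PASS",
                   ifelse(is.na(calls$gene), ".",
                          paste0("GENE=", calls$gene)),
                   "AD:DP",
                   paste0(ref_reads, ",", calls$alt_reads, ":",
                          calls$total_reads),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a single-sample VCF with AD/DP fields into a call table
#'
#' Reads any VCF carrying per-sample \code{AD} (ref,alt) depths, including
#' the dialect written by \code{\link{write_mutation_vcf}}.
#'
#' @param path VCF path.
#' @return Mutation call data frame.
#' @export
read_mutation_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad) || ncol(ad) < 1)
    stop("VCF has no per-sample AD field")
  sample_id <- colnames(ad)[1]
  ad2 <- strsplit(unname(ad[, 1]), ",")
  ref_reads <- as.integer(vapply(ad2, `[[`, "", 1))
  alt_reads <- as.integer(vapply(ad2, `[[`, "", 2))
  fix <- vcfR::getFIX(vcf)
  info <- vcf@fix[, "INFO"]
  gene <- ifelse(!is.na(info) & grepl("GENE=", info),
                 sub(".*GENE=([^;]+).*", "\\1", info), NA_character_)
  data.frame(sample_id = sample_id, chrom = unname(fix[, "CHROM"]),
             pos = as.integer(fix[, "POS"]), ref = unname(fix[, "REF"]),
             alt = unname(fix[, "ALT"]),
             alt_reads = alt_reads, total_reads = ref_reads + alt_reads,
             gene = gene, stringsAsFactors = FALSE)
}

#' Read / write SEG-like copy-number tables
#'
#' Columns: \code{sample_id}, \code{chrom}, \code{start}, \code{end},
#' \code{total_cn}; 1-based inclusive coordinates, segments per chromosome
#' non-overlapping.
#'
#' @param seg Segment data frame.
#' @param path File path.
#' @return The segment data frame (read) or \code{path} (write, invisibly).
#' @export
write_seg <- function(seg, path) {
  utils::write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "start", "end", "total_cn")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("SEG file missing column(s): ", paste(miss, collapse = ", "))
  df$chrom <- as.character(df$chrom)
  if (any(df$total_cn < 1)) stop("SEG file contains total_cn < 1")
  if (any(df$end < df$start)) stop("SEG file contains end < start")
  for (key in unique(paste(df$sample_id, df$chrom))) {
    d <- df[paste(df$sample_id, df$chrom) == key, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)]))
      stop("overlapping segments in SEG file (", key, ")")
  }
  df
}

#' Read a survival table (patient_id, time_days, event)
#'
#' @param path TSV with columns \code{patient_id}, \code{time_days} and
#'   \code{event} coded 0/1.
#' @return Survival record data frame with columns \code{patient_id},
#'   \code{time}, \code{event} (logical).
#' @export
read_survival_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_days", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("survival TSV missing column(s): ", paste(miss, collapse = ", "))
  if (any(!df$event %in% c(0, 1)))
    stop("malformed event flags: need 0 (censored) or 1 (event)")
  data.frame(patient_id = df$patient_id, time = df$time_days,
             event = df$event == 1, stringsAsFactors = FALSE)
}

#' Read a 6x6 combination plate CSV
#'
#' Expected dialect: the first row holds the drug-A concentrations (first
#' field blank or a label), each following row starts with its drug-B
#' concentration followed by the readings. The physical screen layout places
#' the double-vehicle well top-left and the highest doses bottom-right, i.e.
#' concentrations ascend left-to-right and top-to-bottom; this is the default
#' orientation. \code{orientation = "flipped"} reverses both axes for plates
#' laid out the other way around.
#'
#' @param path CSV path.
#' @param drug_a,drug_b Drug labels.
#' @param orientation \code{"plate"} (default, ascending as laid out) or
#'   \code{"flipped"}.
#' @param normalize Divide by the double-vehicle well so viability(0,0) is 1
#'   (default TRUE).
#' @return A \code{dose_matrix}.
#' @export
read_plate_csv <- function(path, drug_a = "drug_a", drug_b = "drug_b",
                           orientation = c("plate", "flipped"),
                           normalize = TRUE) {
  orientation <- match.arg(orientation)
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  conc_a <- as.numeric(raw[1, -1])
  conc_b <- as.numeric(raw[-1, 1])
  v <- as.matrix(raw[-1, -1])
  mode(v) <- "numeric"
  if (anyNA(conc_a) || anyNA(conc_b) || anyNA(v))
    stop("malformed plate CSV: non-numeric concentrations or readings")
  if (orientation == "flipped") {
    conc_a <- rev(conc_a); conc_b <- rev(conc_b)
    v <- v[rev(seq_len(nrow(v))), rev(seq_len(ncol(v))), drop = FALSE]
  }
  oa <- order(conc_a); ob <- order(conc_b)
  conc_a <- conc_a[oa]; conc_b <- conc_b[ob]
  v <- v[ob, oa, drop = FALSE]
  if (conc_a[1] != 0 || conc_b[1] != 0)
    stop("plate layout mismatch: zero-dose (vehicle) level missing")
  if (normalize) {
    if (v[1, 1] <= 0) stop("double-vehicle well is nonpositive")
    v <- v / v[1, 1]
  }
  dimnames(v) <- list(format(conc_b, trim = TRUE),
                      format(conc_a, trim = TRUE))
  dose_matrix(v, conc_a, conc_b, drug_a, drug_b)
}

#' Write a combination plate as CSV in the plate dialect
#'
#' @param mat A \code{dose_matrix}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_plate_csv <- function(mat, path) {
  out <- rbind(c(NA, mat$conc_a), cbind(mat$conc_b, mat$viability))
  utils::write.table(out, path, sep = ",", quote = FALSE, na = "",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
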