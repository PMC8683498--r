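#' clonevolve: clonal evolution analysis for multi-region tumor sequencing
#'
#' Converts somatic variant read counts into cancer cell fractions (CCF),
#' deconvolutes CCF distributions into mutation clusters, reconstructs rooted
#' clone trees with per-biopsy compositions and inter-lesion distances, and
#' provides the cohort-level (Kaplan-Meier, PET response) and pharmacological
#' (relative AUC, ZIP synergy) scoring used alongside such analyses.
#'
#' @keywords internal
#' @aliases clonevolve-package
"_PACKAGE"

## ---------------------------------------------------------------------------
## Scenario construction and validation
## ---------------------------------------------------------------------------

#' Build a simulation scenario (known clone tree + biopsy samples)
#'
#' A scenario fixes the ground truth for the synthetic-data generator: a rooted
#' clone tree with per-sample cancer cell fractions, the number of private
#' mutations carried by each clone, and the sequencing characteristics (purity,
#' mean depth, copy-number profile) of each biopsy.
#'
#' Packaged scenarios:
#' \describe{
#'   \item{\code{"p04_like"}}{Five clones C0--C4 over three biopsies
#'     (peritoneal, liver1, liver2) with CCFs C0 (1,1,1), C1 (1,0,0),
#'     C3 (0.4,0,0), C2 (0,1,1), C4 (0,0,1); 150 private mutations per clone,
#'     purity 0.7, mean depth 150x. The truncal clone carries an EGFR
#'     exon-19-deletion-like marker, the peritoneal lineage an EGFR T790M-like
#'     marker and the liver lineage a BRAF V600E-like marker, so the expected
#'     peritoneal composition is two subclones at 60\%/40\%.}
#'   \item{\code{"single_clone"}}{One clonal population in a single biopsy.}
#'   \item{\code{"two_sample_branching"}}{A truncal clone plus one private
#'     clone per biopsy over two biopsies.}
#' }
#'
#' @param name Name of a packaged scenario (\code{"p04_like"},
#'   \code{"single_clone"}, \code{"two_sample_branching"}) or the path of a
#'   YAML scenario configuration (see \code{\link{write_scenario}}).
#' @param seed Integer seed stored with the scenario; per-sample simulation
#'   seeds are derived from it.
#' @return An object of class \code{clone_scenario}: a list with elements
#'   \code{name}, \code{clones} (data frame: \code{clone_id},
#'   \code{parent_id}, \code{n_private_mutations}), \code{ccf} (clone x sample
#'   matrix of true CCFs), \code{samples} (data frame: \code{sample_id},
#'   \code{purity}, \code{mean_depth}), \code{cn_profiles} (per-sample
#'   SEG-like data frames), \code{mutations} (the deterministic mutation
#'   catalog) and \code{seed}.
#' @examples
#' sc <- build_scenario("p04_like")
#' sc$ccf
#' @export
build_scenario <- function(name = "p04_like", seed = 1L) {
  if (file.exists(name)) {
    return(read_scenario(name))
  }
  sc <- switch(name,
    p04_like = {
      samples <- c("peritoneal", "liver1", "liver2")
      ccf <- rbind(
        C0 = c(1, 1, 1),
        C1 = c(1, 0, 0),
        C3 = c(0.4, 0, 0),
        C2 = c(0, 1, 1),
        C4 = c(0, 0, 1)
      )
      colnames(ccf) <- samples
      clones <- data.frame(
        clone_id  = c("C0", "C1", "C3", "C2", "C4"),
        parent_id = c(NA, "C0", "C1", "C0", "C2"),
        n_private_mutations = 150L,
        stringsAsFactors = FALSE
      )
      marker <- data.frame(
        clone_id = c("C0", "C1", "C2"),
        gene = c("EGFR_del19", "EGFR_T790M", "BRAF_V600E"),
        stringsAsFactors = FALSE
      )
      new_scenario("p04_like", clones, ccf,
                   purity = 0.7, mean_depth = 150, seed = seed,
                   markers = marker)
    },
    single_clone = {
      ccf <- matrix(1, 1, 1, dimnames = list("C0", "S1"))
      clones <- data.frame(clone_id = "C0", parent_id = NA_character_,
                           n_private_mutations = 150L,
                           stringsAsFactors = FALSE)
      new_scenario("single_clone", clones, ccf,
                   purity = 0.7, mean_depth = 150, seed = seed)
    },
    two_sample_branching = {
      ccf <- rbind(C0 = c(1, 1), C1 = c(1, 0), C2 = c(0, 1))
      colnames(ccf) <- c("S1", "S2")
      clones <- data.frame(clone_id = c("C0", "C1", "C2"),
                           parent_id = c(NA, "C0", "C0"),
                           n_private_mutations = 150L,
                           stringsAsFactors = FALSE)
      new_scenario("two_sample_branching", clones, ccf,
                   purity = 0.7, mean_depth = 150, seed = seed)
    },
    stop("unknown scenario name: ", name)
  )
  sc
}

## Internal constructor shared by packaged scenarios and config files.
new_scenario <- function(name, clones, ccf, purity, mean_depth, seed,
                         markers = NULL, cn_profiles = NULL) {
  samples <- data.frame(
    sample_id  = colnames(ccf),
    purity     = rep_len(purity, ncol(ccf)),
    mean_depth = rep_len(mean_depth, ncol(ccf)),
    stringsAsFactors = FALSE
  )
  if (is.null(cn_profiles)) {
    cn_profiles <- lapply(samples$sample_id, function(s) {
      data.frame(chrom = "1", start = 1L, end = 300000000L, total_cn = 2L,
                 stringsAsFactors = FALSE)
    })
    names(cn_profiles) <- samples$sample_id
  }
  sc <- structure(
    list(name = name, clones = clones, ccf = ccf, samples = samples,
         cn_profiles = cn_profiles, seed = as.integer(seed)),
    class = "clone_scenario"
  )
  validate_scenario(sc)
  sc$mutations <- mutation_catalog(sc, markers)
  sc
}

#' Validate a simulation scenario against the clonal sum rule
#'
#' Checks that the clone tree has exactly one root, that every clone's CCF is
#' within \code{[0, 1]} and never exceeds its parent's CCF in any sample, and
#' that in every sample the CCFs of a clone's children sum to at most the
#' clone's own CCF (the pigeonhole/sum rule of subclonal reconstruction).
#'
#' @param scenario A \code{clone_scenario}.
#' @return The scenario, invisibly; stops with an informative error on any
#'   violation.
#' @export
validate_scenario <- function(scenario) {
  cl <- scenario$clones
  ccf <- scenario$ccf
  if (anyDuplicated(cl$clone_id))
    stop("duplicate clone ids in scenario")
  root <- cl$clone_id[is.na(cl$parent_id)]
  if (length(root) != 1L)
    stop("scenario must have exactly one root clone, found ", length(root))
  if (!all(cl$parent_id[!is.na(cl$parent_id)] %in% cl$clone_id))
    stop("parent_id refers to unknown clone")
  if (!setequal(rownames(ccf), cl$clone_id))
    stop("ccf matrix rows must match clone ids")
  if (any(ccf < 0 | ccf > 1))
    stop("clone CCFs must lie in [0, 1]")
  if (any(cl$n_private_mutations < 0))
    stop("n_private_mutations must be >= 0")
  for (i in seq_len(nrow(cl))) {
    p <- cl$parent_id[i]
    if (is.na(p)) next
    bad <- ccf[cl$clone_id[i], ] > ccf[p, ] + 1e-9
    if (any(bad))
      stop("sum-rule violation: clone ", cl$clone_id[i],
           " exceeds parent ", p, " in sample ",
           colnames(ccf)[which(bad)[1]])
  }
  for (id in cl$clone_id) {
    kids <- cl$clone_id[!is.na(cl$parent_id) & cl$parent_id == id]
    if (!length(kids)) next
    tot <- colSums(ccf[kids, , drop = FALSE])
    bad <- tot > ccf[id, ] + 1e-9
    if (any(bad))
      stop("sum-rule violation: children of ", id, " sum to ",
           signif(tot[which(bad)[1]], 4), " > parent CCF in sample ",
           colnames(ccf)[which(bad)[1]])
  }
  invisible(scenario)
}

## Deterministic mutation catalog: each clone contributes n private mutations
## at fixed positions, so mutation keys are harmonized across samples.
mutation_catalog <- function(scenario, markers = NULL) {
  cl <- scenario$clones
  out <- lapply(seq_len(nrow(cl)), function(i) {
    n <- cl$n_private_mutations[i]
    if (n == 0L) return(NULL)
    data.frame(
      chrom = "1",
      pos = (i - 1L) * 1000000L + seq_len(n) * 100L,
      ref = "A", alt = "T",
      gene = paste0(cl$clone_id[i], "_m", seq_len(n)),
      clone_id = cl$clone_id[i],
      stringsAsFactors = FALSE
    )
  })
  cat_df <- do.call(rbind, out)
  if (!is.null(markers)) {
    for (j in seq_len(nrow(markers))) {
      k <- which(cat_df$clone_id == markers$clone_id[j])[1]
      if (!is.na(k)) cat_df$gene[k] <- markers$gene[j]
    }
  }
  rownames(cat_df) <- NULL
  cat_df
}

## ---------------------------------------------------------------------------
## Biopsy simulation
## ---------------------------------------------------------------------------

#' Simulate read counts for one biopsy of a scenario
#'
#' Inverts the CCF correction: for each catalog mutation carried by clone
#' \eqn{c} with multiplicity \eqn{m} (1 throughout), the expected variant
#' allele fraction in a sample with purity \eqn{\rho} and local total copy
#' number \eqn{CN_t} is
#' \deqn{E[VAF] = m \rho CCF_c / (\rho CN_t + (1-\rho) 2).}
#' Sequencing depth is drawn Poisson at the sample's mean depth and variant
#' reads Binomial(depth, E[VAF]). Mutations whose clone is absent from the
#' sample (CCF 0) are emitted with zero variant reads rather than omitted, so
#' that downstream covered-absent handling is exercised.
#'
#' @param scenario A \code{clone_scenario}.
#' @param sample_id One of the scenario's sample ids.
#' @param seed Integer seed; defaults to the scenario seed offset by the
#'   sample index, so each biopsy has its own reproducible stream.
#' @return A data frame of mutation calls: \code{sample_id}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{alt_reads}, \code{total_reads},
#'   \code{gene}.
#' @examples
#' sc <- build_scenario("p04_like")
#' calls <- simulate_biopsy(sc, "peritoneal")
#' head(calls)
#' @export
simulate_biopsy <- function(scenario, sample_id,
                            seed = scenario$seed +
                              match(sample_id, scenario$samples$sample_id)) {
  stopifnot(inherits(scenario, "clone_scenario"))
  i <- match(sample_id, scenario$samples$sample_id)
  if (is.na(i)) stop("unknown sample_id: ", sample_id)
  purity <- scenario$samples$purity[i]
  depth <- scenario$samples$mean_depth[i]
  cat_df <- scenario$mutations
  cn <- cn_at(scenario$cn_profiles[[sample_id]], cat_df$chrom, cat_df$pos)
  ccf <- scenario$ccf[cat_df$clone_id, sample_id]
  m <- 1
  evaf <- m * purity * ccf / (purity * cn + (1 - purity) * 2)
  if (any(evaf > 1 + 1e-9))
    stop("inconsistent scenario: expected VAF > 1 at multiplicity ", m)
  set.seed(seed)
  total <- pmax(stats::rpois(nrow(cat_df), depth), 1L)
  alt <- stats::rbinom(nrow(cat_df), total, evaf)
  data.frame(
    sample_id = sample_id,
    chrom = cat_df$chrom, pos = cat_df$pos,
    ref = cat_df$ref, alt = cat_df$alt,
    alt_reads = alt, total_reads = total,
    gene = cat_df$gene,
    stringsAsFactors = FALSE
  )
}

## Total copy number at positions from a SEG-like profile (1-based inclusive);
## positions not covered by any segment default to diploid.
cn_at <- function(seg, chrom, pos) {
  cn <- rep(2L, length(pos))
  if (is.null(seg) || !nrow(seg)) return(cn)
  for (k in seq_len(nrow(seg))) {
    hit <- chrom == seg$chrom[k] & pos >= seg$start[k] & pos <= seg$end[k]
    cn[hit] <- seg$total_cn[k]
  }
  cn
}

#' Expected variant allele fraction of the simulator
#'
#' Closed form used by \code{\link{simulate_biopsy}}; exposed so that tests
#' and the CCF round trip can evaluate it directly.
#'
#' @param ccf Cancer cell fraction of the clone carrying the mutation.
#' @param purity Tumor purity in (0, 1].
#' @param cn_total Total copy number at the locus (>= 1).
#' @param m Mutation multiplicity (mutated copies per tumor cell).
#' @return Expected VAF.
#' @export
expected_vaf <- function(ccf, purity, cn_total, m = 1) {
  m * purity * ccf / (purity * cn_total + (1 - purity) * 2)
}

## ---------------------------------------------------------------------------
## Dose-response simulation
## ---------------------------------------------------------------------------

#' Simulate a 6x6 drug-combination viability matrix
#'
#' Monotherapy inhibition for each drug follows a log-logistic curve rising
#' from 0 to 1 with the given EC50 and Hill slope; the combination inhibition
#' is the Bliss independence surface \eqn{y_a + y_b - y_a y_b}, plus an
#' optional constant synergy offset \code{delta_true} on cells where both
#' drugs are present, plus Gaussian noise, clipped to \code{[0, 1]}. The plate
#' layout is five threefold dilutions from the starting concentration plus a
#' zero-dose (vehicle control) level on each axis, mirroring a 6x6-well
#' combination screen; viability at (0, 0) is exactly 1.
#'
#' @param ec50_a,ec50_b Monotherapy EC50s (same units as the concentration
#'   axes, nM by convention). Defaults are the starting concentrations of the
#'   default axes, giving a moderate maximal monotherapy effect.
#' @param slopes Length-2 Hill slopes for drugs A and B.
#' @param delta_true Constant inhibition offset added where both doses are
#'   nonzero (0 = exact Bliss independence).
#' @param noise_sd Standard deviation of Gaussian measurement noise on the
#'   inhibition scale; must be >= 0.
#' @param seed Integer seed.
#' @param conc_a,conc_b Ascending concentration axes whose first element is 0.
#' @param drug_a,drug_b Drug labels.
#' @return A \code{dose_matrix}: list with \code{drug_a}, \code{drug_b},
#'   \code{conc_a}, \code{conc_b} and a \code{viability} matrix (rows = B
#'   doses, columns = A doses, both ascending from zero).
#' @examples
#' m <- simulate_dose_response(delta_true = 0, noise_sd = 0, seed = 1)
#' round(m$viability, 3)
#' @export
simulate_dose_response <- function(ec50_a = 300, ec50_b = 100,
                                   slopes = c(1, 1),
                                   delta_true = 0, noise_sd = 0, seed = 1L,
                                   conc_a = c(0, 300 / 3^(4:0)),
                                   conc_b = c(0, 100 / 3^(4:0)),
                                   drug_a = "drug_a", drug_b = "drug_b") {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(conc_a[1] == 0, conc_b[1] == 0,
            !is.unsorted(conc_a), !is.unsorted(conc_b))
  ya <- loglogistic_inhibition(conc_a, ec50_a, slopes[1])
  yb <- loglogistic_inhibition(conc_b, ec50_b, slopes[2])
  inh <- outer(yb, ya, function(b, a) a + b - a * b)
  both <- outer(conc_b > 0, conc_a > 0, "&")
  inh[both] <- inh[both] + delta_true
  set.seed(seed)
  noise <- matrix(stats::rnorm(length(inh), 0, noise_sd),
                  nrow(inh), ncol(inh))
  inh <- pmin(pmax(inh + noise, 0), 1)
  inh[1, 1] <- 0
  v <- 1 - inh
  dimnames(v) <- list(format(conc_b, trim = TRUE),
                      format(conc_a, trim = TRUE))
  dose_matrix(v, conc_a, conc_b, drug_a, drug_b)
}

## 0-to-1 log-logistic inhibition; 0 dose -> 0 effect.
loglogistic_inhibition <- function(x, ec50, slope) {
  y <- numeric(length(x))
  nz <- x > 0
  y[nz] <- 1 / (1 + (ec50 / x[nz])^slope)
  y
}

#' Construct a dose-response matrix object
#'
#' @param viability Numeric matrix (rows = drug-B doses, columns = drug-A
#'   doses), normalized so the (0, 0) well is 1.
#' @param conc_a,conc_b Ascending concentration axes; first element 0.
#' @param drug_a,drug_b Drug labels.
#' @return A \code{dose_matrix} object.
#' @export
dose_matrix <- function(viability, conc_a, conc_b,
                        drug_a = "drug_a", drug_b = "drug_b") {
  stopifnot(is.matrix(viability),
            nrow(viability) == length(conc_b),
            ncol(viability) == length(conc_a))
  structure(list(drug_a = drug_a, drug_b = drug_b,
                 conc_a = conc_a, conc_b = conc_b,
                 viability = viability),
            class = "dose_matrix")
}

## ---------------------------------------------------------------------------
## Packaged survival table
## ---------------------------------------------------------------------------

#' Packaged overall-survival table for the six-patient resistance cohort
#'
#' Overall survival in days from detection of acquired resistance, for the six
#' evaluable patients: one alive at last follow-up (censored), five deceased
#' (events).
#'
#' @return A data frame of survival records: \code{patient_id}, \code{time}
#'   (days), \code{event} (TRUE = death observed, FALSE = censored).
#' @examples
#' packaged_survival_table()
#' @export
packaged_survival_table <- function() {
  data.frame(
    patient_id = c("P01", "P04", "P12", "P13", "P14", "P15"),
    time  = c(636, 287, 101, 239, 359, 219),
    event = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

## ---------------------------------------------------------------------------
## Scenario serialization (YAML config)
## ---------------------------------------------------------------------------

#' Write / read a scenario configuration file
#'
#' Scenarios round-trip through a YAML file with nested \code{clones} (id,
#' parent, private mutation count, per-sample CCF map) and \code{samples}
#' (purity, mean depth, optional copy-number segments) blocks. Reading
#' re-validates the sum rule, so a config whose child CCF exceeds its
#' parent's is rejected.
#'
#' @param scenario A \code{clone_scenario}.
#' @param path File path.
#' @return \code{write_scenario} returns \code{path} invisibly;
#'   \code{read_scenario} returns a validated \code{clone_scenario}.
#' @export
write_scenario <- function(scenario, path) {
  cl <- scenario$clones
  clones <- lapply(seq_len(nrow(cl)), function(i) {
    list(clone_id = cl$clone_id[i],
         parent_id = if (is.na(cl$parent_id[i])) NULL else cl$parent_id[i],
         n_private_mutations = cl$n_private_mutations[i],
         ccf = as.list(scenario$ccf[cl$clone_id[i], ]))
  })
  ss <- scenario$samples
  samples <- lapply(seq_len(nrow(ss)), function(i) {
    list(sample_id = ss$sample_id[i], purity = ss$purity[i],
         mean_depth = ss$mean_depth[i])
  })
  yaml::write_yaml(list(name = scenario$name, seed = scenario$seed,
                        clones = clones, samples = samples), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  sample_ids <- vapply(cfg$samples, `[[`, "", "sample_id")
  ccf <- t(vapply(cfg$clones,
                  function(c) unlist(c$ccf)[sample_ids],
                  numeric(length(sample_ids))))
  rownames(ccf) <- vapply(cfg$clones, `[[`, "", "clone_id")
  colnames(ccf) <- sample_ids
  clones <- data.frame(
    clone_id = rownames(ccf),
    parent_id = vapply(cfg$clones,
                       function(c) if (is.null(c$parent_id)) NA_character_
                                   else c$parent_id, ""),
    n_private_mutations =
      vapply(cfg$clones, function(c) as.integer(c$n_private_mutations), 1L),
    stringsAsFactors = FALSE
  )
  new_scenario(cfg$name %||% basename(path), clones, ccf,
               purity = vapply(cfg$samples, `[[`, 1, "purity"),
               mean_depth = vapply(cfg$samples, `[[`, 1, "mean_depth"),
               seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
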