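#' Reference single-molecule footprint composition at CTCF motifs
#'
#' Published single-molecule GpC footprinting at CTCF motifs finds roughly
#' 43% of reads carrying a CTCF footprint, 42% nucleosomal and 15% unbound,
#' with fully protected molecules making up about 60% of the CTCF-bound
#' reads.  These values are used to calibrate the read-class mixture of the
#' synthetic generator.
#'
#' @return named list with `class_fractions` (ctcf_bound, nucleosomal,
#'   unbound) and `protected_share` (fraction of CTCF-bound reads that are
#'   fully protected).
#' @export
ctcf_read_class_reference <- function() {
  list(
    class_fractions = c(ctcf_bound = 0.43, nucleosomal = 0.42, unbound = 0.15),
    protected_share = 0.60
  )
}

#' Reference per-ZF GpC protection at CTCF-bound sites
#'
#' Mean triplet protection (1 - methylated fraction) per zinc finger at
#' CTCF-bound sites, as measured genome-wide by nanopore GpC footprinting.
#' ZF5 is typically excluded from measurement because of low GpC occurrence
#' in its triplet; a core-like placeholder is supplied here so the generator
#' can still protect it.
#'
#' @return named numeric vector of length 11 (`ZF1`..`ZF11`).
#' @export
ctcf_zf_protection_reference <- function() {
  c(ZF1 = 0.80, ZF2 = 0.85, ZF3 = 0.94, ZF4 = 0.96, ZF5 = 0.96,
    ZF6 = 0.97, ZF7 = 0.96, ZF8 = 0.96, ZF9 = 0.90, ZF10 = 0.84,
    ZF11 = 0.78)
}

#' Invert the labeling model to calibrate per-ZF binding probabilities
#'
#' Observed protection mixes true ZF binding with imperfect enzymatic
#' labeling: an accessible GpC is methylated with probability
#' `label_efficiency` and a protected GpC with probability `background`.
#' The observed protection of a ZF bound with probability q is
#' `1 - (q * background + (1 - q) * label_efficiency)`, so the binding
#' probability that reproduces a target protection P is
#' `q = (label_efficiency - (1 - P)) / (label_efficiency - background)`.
#' Values outside `[0, 1]` are clipped and flagged: with a 5% background no
#' observable protection can exceed 0.95, so targets above that saturate at
#' q = 1.
#'
#' @param target named numeric vector of target observed protections.
#' @param label_efficiency probability an accessible GpC is methylated.
#' @param background probability a protected GpC is methylated.
#' @param protected_share fraction of CTCF-bound reads that are fully
#'   protected (all ZFs bound); the remaining reads carry the per-ZF
#'   probabilities, so the partial-read probability is back-computed as
#'   `(q - protected_share) / (1 - protected_share)`.
#' @return data.frame with columns `zf`, `target`, `q_total` (marginal
#'   binding probability over CTCF-bound reads), `q_partial` (binding
#'   probability within partially protected reads) and `clipped`.
#' @export
calibrate_zf_protection <- function(target = ctcf_zf_protection_reference(),
                                    label_efficiency = 0.85,
                                    background = 0.05,
                                    protected_share = 0.60) {
  stopifnot(label_efficiency > background)
  q <- (label_efficiency - (1 - target)) / (label_efficiency - background)
  clipped <- q < 0 | q > 1
  q <- pmin(pmax(q, 0), 1)
  qp <- (q - protected_share) / (1 - protected_share)
  qp_clipped <- qp < 0 | qp > 1
  qp <- pmin(pmax(qp, 0), 1)
  data.frame(
    zf = names(target), target = unname(target), q_total = unname(q),
    q_partial = unname(qp), clipped = unname(clipped | qp_clipped),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic GpC footprint generator
#'
#' Defines a population of single reads at CTCF motifs as a mixture of four
#' archetypes: `ctcf_full` (all ZF triplets protected), `ctcf_partial` (core
#' ZFs 3-8 protected, each peripheral ZF protected independently with its
#' `zf_protection_prob`), `nucleosomal` (a 147-bp window containing the
#' motif protected) and `unbound` (nothing protected).  GpC sites are placed
#' on a regular grid; accessible sites are methylated with
#' `label_efficiency`, protected sites with `background_methylation`, and
#' calls are dropped to missing with `missing_rate`.
#'
#' @param n_motifs,reads_per_motif dataset size.
#' @param class_mixture named probabilities over
#'   `c("ctcf_full","ctcf_partial","nucleosomal","unbound")`; must sum to 1.
#' @param zf_protection_prob probability that each peripheral ZF
#'   (1, 2, 9, 10, 11) is bound in a `ctcf_partial` read; scalar or a named
#'   vector `ZF1`..`ZF11` (core entries are ignored, core ZFs are always
#'   bound in CTCF reads).
#' @param gpc_spacing grid spacing in bp.  The default of 3 bp places
#'   exactly one site in every 3-bp ZF window; coarser grids can leave ZF
#'   windows siteless, which is rejected when `require_zf_coverage` is TRUE.
#' @param label_efficiency,background_methylation,missing_rate labeling model.
#' @param window motif-relative extent of generated sites (bp).
#' @param nucleosome_width width of the nucleosomal protected window (bp).
#' @param require_zf_coverage reject grids that miss a ZF window entirely.
#' @param zfmap a ZF window map, see [zf_map()].
#' @param seed integer RNG seed.
#' @return an object of class `footprint_sim_config`.
#' @export
footprint_sim_config <- function(n_motifs = 100L,
                                 reads_per_motif = 100L,
                                 class_mixture = c(ctcf_full = 0.258,
                                                   ctcf_partial = 0.172,
                                                   nucleosomal = 0.42,
                                                   unbound = 0.15),
                                 zf_protection_prob = 0.6,
                                 gpc_spacing = 3L,
                                 label_efficiency = 0.85,
                                 background_methylation = 0.05,
                                 missing_rate = 0.05,
                                 window = c(-120L, 120L),
                                 nucleosome_width = 147L,
                                 require_zf_coverage = TRUE,
                                 zfmap = zf_map(),
                                 seed = 1L) {
  classes <- c("ctcf_full", "ctcf_partial", "nucleosomal", "unbound")
  if (!all(classes %in% names(class_mixture)))
    stop("class_mixture must be named over ", paste(classes, collapse = ", "))
  class_mixture <- class_mixture[classes]
  if (abs(sum(class_mixture) - 1) > 1e-12)
    stop("class_mixture must sum to 1")
  probs <- c(class_mixture, label_efficiency, background_methylation,
             missing_rate, zf_protection_prob)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (gpc_spacing < 1) stop("gpc_spacing must be >= 1")
  if (length(zf_protection_prob) == 1L) {
    zf_protection_prob <- stats::setNames(rep(zf_protection_prob, 11),
                                          zf_numbers())
  }
  if (!all(zf_numbers() %in% names(zf_protection_prob)))
    stop("zf_protection_prob must be scalar or named ZF1..ZF11")
  sites <- seq.int(window[1], window[2], by = gpc_spacing)
  if (require_zf_coverage) {
    reg <- zf_region_of(sites, zfmap)
    missing_zf <- setdiff(zfmap$region[zfmap$type == "zf"],
                          unique(reg[!is.na(reg)]))
    if (length(missing_zf) > 0)
      stop("gpc_spacing ", gpc_spacing, " leaves ZF window(s) without a site: ",
           paste(missing_zf, collapse = ", "))
  }
  structure(list(
    n_motifs = as.integer(n_motifs),
    reads_per_motif = as.integer(reads_per_motif),
    class_mixture = class_mixture,
    zf_protection_prob = zf_protection_prob[zf_numbers()],
    gpc_spacing = as.integer(gpc_spacing),
    label_efficiency = label_efficiency,
    background_methylation = background_methylation,
    missing_rate = missing_rate,
    window = as.integer(window),
    nucleosome_width = as.integer(nucleosome_width),
    zfmap = zfmap,
    seed = as.integer(seed)
  ), class = "footprint_sim_config")
}

#' Generate synthetic per-read GpC methylation calls with ground truth
#'
#' Draws a read class per read from the configured mixture, lays down the
#' class's protection pattern over the GpC grid, methylates accessible sites
#' with `label_efficiency` and protected sites with
#' `background_methylation`, and drops calls to missing with `missing_rate`.
#' Deterministic under the config seed.
#'
#' @param cfg a [footprint_sim_config()].
#' @return list with elements
#'   \describe{
#'     \item{calls}{data.frame `read_id, motif_id, rel_pos, call` with call
#'       in `"M"`, `"U"`, `"."`.}
#'     \item{truth}{list with `classes` (per-read class and, for CTCF reads,
#'       whether fully protected) and `zf_bound` (per-read logical flags
#'       `ZF1`..`ZF11`, `NA` for non-CTCF reads).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
gen_methyl_reads <- function(cfg) {
  stopifnot(inherits(cfg, "footprint_sim_config"))
  set.seed(cfg$seed)
  sites <- seq.int(cfg$window[1], cfg$window[2], by = cfg$gpc_spacing)
  S <- length(sites)
  N <- cfg$n_motifs * cfg$reads_per_motif
  motif_id <- rep(sprintf("motif_%05d", seq_len(cfg$n_motifs)),
                  each = cfg$reads_per_motif)
  read_id <- sprintf("%s_read_%04d", motif_id,
                     rep(seq_len(cfg$reads_per_motif), cfg$n_motifs))
  classes <- c("ctcf_full", "ctcf_partial", "nucleosomal", "unbound")
  cls <- sample(classes, N, replace = TRUE, prob = cfg$class_mixture)

  region <- zf_region_of(sites, cfg$zfmap)
  is_zf_site <- !is.na(region) & region %in% zf_numbers()
  zf_of_site <- ifelse(is_zf_site, region, NA_character_)
  core_zf <- paste0("ZF", 3:8)
  periph_zf <- setdiff(zf_numbers(), core_zf)
  half_nuc <- cfg$nucleosome_width %/% 2L
  in_nuc <- abs(sites) <= half_nuc

  # per-read per-ZF bound flags (CTCF classes only)
  zf_bound <- matrix(NA, nrow = N, ncol = 11,
                     dimnames = list(NULL, zf_numbers()))
  is_ctcf <- cls %in% c("ctcf_full", "ctcf_partial")
  zf_bound[is_ctcf, ] <- TRUE
  part <- which(cls == "ctcf_partial")
  for (zf in periph_zf) {
    zf_bound[part, zf] <- stats::runif(length(part)) < cfg$zf_protection_prob[zf]
  }

  # N x S protection matrix
  protected <- matrix(FALSE, nrow = N, ncol = S)
  if (any(is_ctcf)) {
    for (s in which(is_zf_site)) {
      protected[is_ctcf, s] <- zf_bound[is_ctcf, zf_of_site[s]]
    }
  }
  nuc <- cls == "nucleosomal"
  if (any(nuc)) protected[nuc, in_nuc] <- TRUE

  p_meth <- ifelse(protected, cfg$background_methylation, cfg$label_efficiency)
  meth <- matrix(stats::runif(N * S) < p_meth, nrow = N)
  miss <- matrix(stats::runif(N * S) < cfg$missing_rate, nrow = N)
  call <- matrix("U", nrow = N, ncol = S)
  call[meth] <- "M"
  call[miss] <- "."

  calls <- data.frame(
    read_id = rep(read_id, each = S),
    motif_id = rep(motif_id, each = S),
    rel_pos = rep(sites, N),
    call = as.vector(t(call)),
    stringsAsFactors = FALSE
  )
  truth_classes <- data.frame(
    read_id = read_id, motif_id = motif_id, class = cls,
    fully_protected = ifelse(is_ctcf, cls == "ctcf_full", NA),
    stringsAsFactors = FALSE
  )
  zf_df <- as.data.frame(zf_bound)
  zf_df <- cbind(data.frame(read_id = read_id, stringsAsFactors = FALSE), zf_df)
  list(calls = calls, truth = list(classes = truth_classes, zf_bound = zf_df),
       config = cfg)
}
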