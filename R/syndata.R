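# Synthetic BFU-E cohort generator.
#
# Emulates a plate-based deep scRNA-seq cohort of erythroid progenitors with
# four clinical groups (NC, UT, GCR, GCNR), five latent subpopulations
# (C0 translation-high, C1 TF-high, C2 G2/M, C3 G1/S-replication,
# C4 erythroid-primed), per-plate biological batch-control cells, planted
# group-specific gene-program shifts, and optional low-quality / doublet
# spike-ins whose construction is tied to the QC thresholds. Counts are
# negative binomial (gamma-Poisson) around a per-cell depth drawn from a
# log-normal, calibrated so the default cohort matches the reported depth
# (median 122,477 UMIs) and detection (mean 3,594 genes per cell).

SUBPOPS <- paste0("C", 0:4)

.marker_set_names <- c(
  C0 = "marker_C0_translation",
  C1 = "marker_C1_tf",
  C2 = "marker_C2_mitosis",
  C3 = "marker_C3_g1s_replication",
  C4 = "marker_C4_erythroid_gata1"
)

.functional_set_sizes <- c(
  ribosomal_proteins = 80L,
  apoptosis = 40L,
  p53_signaling = 40L,
  g1s_transition = 40L,
  dna_replication = 40L,
  type1_ifn = 40L,
  proliferation = 40L,
  s_phase = 80L,
  g2m_phase = 80L
)

.default_subpop_proportions <- function(groups) {
  full <- rbind(
    NC   = c(0.32, 0.22, 0.14, 0.12, 0.20),
    UT   = c(0.30, 0.21, 0.14, 0.27, 0.08),
    GCR  = c(0.31, 0.21, 0.14, 0.16, 0.18),
    GCNR = c(0.33, 0.24, 0.05, 0.28, 0.10)
  )
  colnames(full) <- SUBPOPS
  full[intersect(groups, rownames(full)), , drop = FALSE]
}

.default_phase_proportions <- function(groups) {
  # C2/C3 are the actively cycling compartments; C0/C1 (self-renewal,
  # translation/TF programs) and the erythroid-primed C4 are mostly G1.
  base <- rbind(
    C0 = c(0.80, 0.13, 0.07),
    C1 = c(0.80, 0.13, 0.07),
    C2 = c(0.10, 0.20, 0.70),
    C3 = c(0.20, 0.65, 0.15),
    C4 = c(0.70, 0.18, 0.12)
  )
  colnames(base) <- c("G1", "S", "G2M")
  out <- purrr::map(groups, function(g) {
    m <- base
    # Patient-group C3 cells are pushed further into S phase (forced S entry).
    if (g %in% c("UT", "GCR", "GCNR")) m["C3", ] <- c(0.10, 0.78, 0.12)
    tibble(
      group = g, subpop = rownames(m),
      G1 = m[, "G1"], S = m[, "S"], G2M = m[, "G2M"]
    )
  })
  list_rbind(out)
}

.default_program_effects <- function(groups) {
  eff <- list()
  for (g in intersect(c("UT", "GCNR"), groups)) {
    eff[[g]] <- tibble(
      group = g,
      subpop = c("C3", "C3", "C3", "C4", "C3", "C4", "C3"),
      set = c("g1s_transition", "dna_replication", "apoptosis", "apoptosis",
              "p53_signaling", "p53_signaling", "proliferation"),
      log2fc = c(0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.5)
    )
  }
  if ("GCR" %in% groups) {
    eff[["GCR"]] <- bind_rows(
      tibble(group = "GCR", subpop = "C3", set = "type1_ifn", log2fc = 1.0),
      tibble(group = "GCR", subpop = "C3", set = "proliferation", log2fc = -0.5),
      tibble(group = "GCR", subpop = SUBPOPS, set = "ribosomal_proteins", log2fc = -0.4)
    )
  }
  out <- list_rbind(eff)
  if (is.null(out)) {
    out <- tibble(group = character(), subpop = character(),
                  set = character(), log2fc = numeric())
  }
  out
}

# Expected number of detected genes for a cell of total depth `depth`, given
# normalized gene abundances `abund` and NB size `size` (possibly per the sum
# of `n_cells` independent cells of that depth each).
.expected_detected <- function(depth, abund, size, n_cells = 1) {
  mu <- depth * abund
  sum(1 - (size / (size + mu))^(size * n_cells))
}

.abundance_multiset <- function(n_genes, sigma) {
  a <- exp(sigma * qnorm(ppoints(n_genes)))
  a / sum(a)
}

# Solve the abundance spread so the depth-averaged expected detected-gene
# count matches the calibration target. The subpopulation program boosts
# renormalize mass away from background genes (the C0 ribosomal-protein
# boost in particular, since RP genes carry the largest abundance share), so
# each subpopulation contributes with an effective depth D / r_k, where r_k
# is its renormalization factor; the expectation is averaged over the
# subpopulation mixture and the per-cell depth distribution.
.calibrate_gene_sigma <- function(cfg, target) {
  size <- 1 / cfg$nb_dispersion
  n <- cfg$n_genes
  depths <- stats::qlnorm(ppoints(41), cfg$depth_lognormal[["meanlog"]],
                          cfg$depth_lognormal[["sdlog"]])
  sp <- cfg$subpop_proportions
  w <- if ("NC" %in% rownames(sp)) sp["NC", ] else sp[1, ]
  n_rp <- .functional_set_sizes[["ribosomal_proteins"]]
  # mass boosted in every cell: its marker block, plus (for cycling cells)
  # one phase set; random placement => expected mass share = set size / n
  n_phase <- .functional_set_sizes[["s_phase"]]
  boost_common <- (2^cfg$subpop_marker_log2fc - 1) * cfg$marker_block_size / n +
    0.5 * (2^cfg$phase_log2fc - 1) * n_phase / n
  f <- function(sigma) {
    a <- .abundance_multiset(n, sigma)
    m_rp <- sum(utils::tail(a, n_rp))  # RP genes take the top quantiles
    r <- rep(1 + boost_common, length(w))
    r[1] <- r[1] + (2^cfg$c0_rp_log2fc - 1) * m_rp  # C0
    e_det <- 0
    for (k in seq_along(w)) {
      if (w[k] == 0) next
      e_det <- e_det + w[k] * mean(vapply(
        depths, function(D) .expected_detected(D / r[k], a, size), numeric(1)
      ))
    }
    e_det - target
  }
  lo <- f(0.2); hi <- f(8)
  if (lo < 0 || hi > 0) {
    abort("Detected-gene target is not attainable for this n_genes/depth; adjust `mean_detected_target`.")
  }
  uniroot(f, c(0.2, 8), tol = 1e-4)$root
}

# Depth-inflation factor for doublet spike-ins: the sum of two cells at this
# factor times the usual depth must exceed the doublet gene threshold by
# construction. The factor is solved at the 1st percentile of the parent
# depth distribution with an 8% margin, so even unlucky depth draws and the
# detected-gene loss from the downstream gene filter leave doublets above
# the cutoff.
.calibrate_doublet_factor <- function(n_genes, sigma, depth_lognormal,
                                      nb_dispersion, min_genes) {
  size <- 1 / nb_dispersion
  a <- .abundance_multiset(n_genes, sigma)
  d_lo <- stats::qlnorm(0.01, depth_lognormal[["meanlog"]],
                        depth_lognormal[["sdlog"]])
  target <- min(1.08 * min_genes, 0.97 * n_genes)
  f <- function(log10f) {
    .expected_detected(10^log10f * d_lo, a, size, n_cells = 2) - target
  }
  if (f(0) >= 0) return(1)
  if (f(6) < 0) abort("Doublet gene threshold not attainable at any depth; lower `doublet_min_genes`.")
  10^uniroot(f, c(0, 6), tol = 1e-4)$root
}

#' Build a synthetic-cohort configuration
#'
#' Returns the fully populated configuration for [simulate_cohort()], with
#' defaults matching the study conditions of the modeled cohort: four groups
#' of 426 (NC), 428 (UT), 276 (GCR) and 262 (GCNR) cells, five latent
#' subpopulations with disjoint 60-gene marker programs, 96-well plates with
#' 16 batch-control cells each (drawn from one designated NC donor and
#' counted within the NC group), depth calibrated to a median of 122,477
#' total UMIs and a mean of 3,594 detected genes per cell, and planted
#' program shifts: UT/GCNR elevate G1/S-transition, DNA-replication,
#' apoptosis and P53 programs with C3 enriched and C4 depleted (GCNR also
#' depletes C2); GCR elevates the type 1 interferon program and lowers
#' proliferation and ribosomal-protein expression.
#'
#' @param ... Named overrides of configuration fields. `group_sizes` and
#'   `subpop_proportions` may be partial (named by group) and are merged into
#'   the defaults. Unknown field names are an error.
#' @return A list of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(groups = "NC", group_sizes = c(NC = 60), n_genes = 1200,
#'                     mean_detected_target = 400, doublet_min_genes = 1000,
#'                     controls_per_plate = 4)
#' sum(cfg$group_sizes)
synth_config <- function(...) {
  overrides <- list(...)
  if (length(overrides) == 1 && is.null(names(overrides)) &&
      is.list(overrides[[1]])) {
    overrides <- overrides[[1]]
  }
  defaults <- list(
    n_genes = 16000L,
    groups = NULL,
    group_sizes = c(NC = 426L, UT = 428L, GCR = 276L, GCNR = 262L),
    donors_per_group = 4L,
    subpop_proportions = NULL,
    phase_proportions = NULL,
    program_effects = NULL,
    marker_block_size = 60L,
    subpop_marker_log2fc = 2.5,
    c0_rp_log2fc = 0.8,
    phase_log2fc = 1.1,
    depth_lognormal = c(meanlog = log(122477), sdlog = 0.35),
    nb_dispersion = 0.3,
    mean_detected_target = 3594,
    plate_size = 96L,
    controls_per_plate = 16L,
    spikein_low_quality_per_group = 0L,
    spikein_doublet_per_group = 0L,
    low_quality_depth = 800,
    doublet_min_genes = 10000L,
    gene_sigma = NULL,
    doublet_depth_factor = NULL,
    seed = 1L
  )
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(paste0("Unknown synth_config field(s): ", paste(unknown, collapse = ", ")))
  }

  cfg <- defaults
  # group_sizes: partial overrides merge into the defaults by name
  if (!is.null(overrides$group_sizes)) {
    gs <- overrides$group_sizes
    if (is.null(names(gs))) abort("`group_sizes` must be a named vector.")
    if (all(names(gs) %in% names(defaults$group_sizes))) {
      full <- defaults$group_sizes
      full[names(gs)] <- gs
      gs <- full
    }
    cfg$group_sizes <- gs
    overrides$group_sizes <- NULL
  }
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  if (!is.null(cfg$groups)) {
    missing_g <- setdiff(cfg$groups, names(cfg$group_sizes))
    if (length(missing_g)) {
      abort(paste0("Unknown group(s) in `groups`: ", paste(missing_g, collapse = ", ")))
    }
    cfg$group_sizes <- cfg$group_sizes[cfg$groups]
  }
  groups <- names(cfg$group_sizes)

  # subpop proportions: matrix groups x 5, partial row overrides allowed
  sp_default <- .default_subpop_proportions(groups)
  if (nrow(sp_default) < length(groups)) {
    missing_g <- setdiff(groups, rownames(sp_default))
    extra <- matrix(rep(c(0.32, 0.22, 0.14, 0.12, 0.20), length(missing_g)),
                    nrow = length(missing_g), byrow = TRUE,
                    dimnames = list(missing_g, SUBPOPS))
    sp_default <- rbind(sp_default, extra)[groups, , drop = FALSE]
  }
  sp <- cfg$subpop_proportions
  if (is.null(sp)) {
    sp <- sp_default
  } else if (is.list(sp) && !is.data.frame(sp)) {
    m <- sp_default
    for (g in names(sp)) m[g, ] <- sp[[g]]
    sp <- m
  } else {
    sp <- as.matrix(sp)
    if (is.null(colnames(sp))) colnames(sp) <- SUBPOPS
  }
  sp <- sp[groups, , drop = FALSE]
  if (any(sp < 0)) abort("subpop_proportions must be non-negative.")
  if (any(abs(rowSums(sp) - 1) > 1e-9)) {
    abort("subpop_proportions rows must sum to 1.")
  }
  cfg$subpop_proportions <- sp

  if (is.null(cfg$phase_proportions)) {
    cfg$phase_proportions <- .default_phase_proportions(groups)
  }
  if (is.null(cfg$program_effects)) {
    cfg$program_effects <- .default_program_effects(groups)
  }

  if (any(cfg$group_sizes <= 0)) abort("group_sizes must be positive.")
  if (cfg$nb_dispersion <= 0) abort("nb_dispersion must be positive.")
  if (cfg$plate_size < cfg$controls_per_plate) {
    abort("plate_size must be at least controls_per_plate.")
  }
  n_set_genes <- 5L * cfg$marker_block_size + sum(.functional_set_sizes)
  if (cfg$n_genes < n_set_genes) {
    abort(sprintf("n_genes (%d) is smaller than the union of program gene sets (%d).",
                  cfg$n_genes, n_set_genes))
  }

  if (is.null(cfg$gene_sigma)) {
    cfg$gene_sigma <- .calibrate_gene_sigma(cfg, cfg$mean_detected_target)
  }
  if (is.null(cfg$doublet_depth_factor)) {
    cfg$doublet_depth_factor <- .calibrate_doublet_factor(
      cfg$n_genes, cfg$gene_sigma, cfg$depth_lognormal, cfg$nb_dispersion,
      cfg$doublet_min_genes
    )
  }
  structure(cfg, class = "synth_config")
}

# Gene identifiers and program gene sets as disjoint index blocks.
.build_gene_sets <- function(cfg) {
  width <- max(5, nchar(as.character(cfg$n_genes)))
  genes <- sprintf(paste0("g%0", width, "d"), seq_len(cfg$n_genes))
  sizes <- c(setNames(rep(cfg$marker_block_size, 5), .marker_set_names),
             .functional_set_sizes)
  idx <- 0L
  sets <- list()
  for (nm in names(sizes)) {
    sets[[nm]] <- genes[(idx + 1L):(idx + sizes[[nm]])]
    idx <- idx + sizes[[nm]]
  }
  list(genes = genes, sets = sets)
}

# Per-(group effects, subpop, phase) normalized expression profile.
.profile_for <- function(base_abund, gene_sets, cfg, effects, subpop, phase) {
  n <- length(base_abund)
  log2m <- numeric(n)
  gidx <- function(set) match(gene_sets$sets[[set]], gene_sets$genes)
  if (!is.na(subpop)) {
    log2m[gidx(.marker_set_names[[subpop]])] <-
      log2m[gidx(.marker_set_names[[subpop]])] + cfg$subpop_marker_log2fc
    if (subpop == "C0") {
      log2m[gidx("ribosomal_proteins")] <-
        log2m[gidx("ribosomal_proteins")] + cfg$c0_rp_log2fc
    }
    if (nrow(effects)) {
      for (i in seq_len(nrow(effects))) {
        if (effects$subpop[i] == subpop) {
          j <- gidx(effects$set[i])
          log2m[j] <- log2m[j] + effects$log2fc[i]
        }
      }
    }
  }
  if (!is.na(phase)) {
    if (phase == "S") {
      log2m[gidx("s_phase")] <- log2m[gidx("s_phase")] + cfg$phase_log2fc
    } else if (phase == "G2M") {
      log2m[gidx("g2m_phase")] <- log2m[gidx("g2m_phase")] + cfg$phase_log2fc
    }
  }
  p <- base_abund * 2^log2m
  p / sum(p)
}

#' Simulate a synthetic erythroid-progenitor cohort
#'
#' Draws a cells-by-genes UMI count matrix with the latent structure
#' described in [synth_config()], together with cell annotations and a
#' ground-truth channel for recovery tests. Fully reproducible from
#' `config$seed`.
#'
#' @param config A `synth_config` object.
#' @return A list of class `synth_cohort` with elements `counts` (sparse
#'   cells x genes `dgCMatrix`), `annotations` (tibble: cell, group, donor,
#'   plate, is_control), `truth` (tibble: cell, subpop, phase, spikein_kind),
#'   `gene_sets` (named list, the planted programs), `planted_effects`
#'   (gene-level tibble of planted log2 fold changes) and `config`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "synth_config")) config <- synth_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    gs <- .build_gene_sets(cfg)
    groups <- names(cfg$group_sizes)

    # -- gene abundances: fixed multiset; ribosomal-protein genes take the
    # top quantiles (they are the highest-expressed module in these cells),
    # cell-cycle phase genes take the 85th-97th percentile band (canonical
    # S / G2M markers are well-expressed genes), the rest are permuted at
    # random.
    n <- cfg$n_genes
    a_sorted <- .abundance_multiset(n, cfg$gene_sigma)
    rp_idx <- match(gs$sets$ribosomal_proteins, gs$genes)
    phase_idx <- match(c(gs$sets$s_phase, gs$sets$g2m_phase), gs$genes)
    abund <- numeric(n)
    rank_pool <- seq_len(n)
    rp_ranks <- utils::tail(rank_pool, length(rp_idx))
    band <- setdiff(seq.int(floor(0.85 * n), floor(0.97 * n)), rp_ranks)
    if (length(band) < length(phase_idx)) {
      # small gene universes: widen the band downward as far as needed
      band <- utils::tail(setdiff(seq_len(floor(0.97 * n)), rp_ranks),
                          length(phase_idx))
    }
    phase_ranks <- sample(band, length(phase_idx))
    abund[rp_idx] <- sample(a_sorted[rp_ranks])
    abund[phase_idx] <- a_sorted[phase_ranks]
    rest_idx <- setdiff(rank_pool, c(rp_idx, phase_idx))
    rest_ranks <- setdiff(rank_pool, c(rp_ranks, phase_ranks))
    abund[rest_idx] <- sample(a_sorted[rest_ranks])

    # -- cell bookkeeping
    n_spike <- (cfg$spikein_low_quality_per_group +
                  cfg$spikein_doublet_per_group) * length(groups)
    total_cells <- sum(cfg$group_sizes) + n_spike
    n_plates <- ceiling(total_cells / cfg$plate_size)
    n_controls <- cfg$controls_per_plate * n_plates
    if (n_controls > 0) {
      if (!"NC" %in% groups) {
        abort("Batch controls require an NC group (or set controls_per_plate = 0).")
      }
      if (cfg$group_sizes[["NC"]] <= n_controls) {
        abort(sprintf("NC group (%d cells) cannot supply %d batch controls.",
                      cfg$group_sizes[["NC"]], n_controls))
      }
    }

    sample_subpop <- function(group, n) {
      sample(SUBPOPS, n, replace = TRUE, prob = cfg$subpop_proportions[group, ])
    }
    sample_phase <- function(group, subpops) {
      pp <- cfg$phase_proportions
      vapply(subpops, function(sp) {
        row <- pp[pp$group == group & pp$subpop == sp, , drop = FALSE]
        sample(c("G1", "S", "G2M"), 1, prob = c(row$G1, row$S, row$G2M))
      }, character(1), USE.NAMES = FALSE)
    }

    rows <- list()
    for (g in groups) {
      n_exp <- cfg$group_sizes[[g]] - if (g == "NC") n_controls else 0L
      donors <- paste0(g, "_d", seq_len(cfg$donors_per_group))
      if (g == "NC" && n_controls > 0 && cfg$donors_per_group > 1) {
        donors <- donors[-1]  # donor 1 is the designated control donor
      }
      sp <- sample_subpop(g, n_exp)
      rows[[g]] <- tibble(
        group = g,
        donor = rep(donors, length.out = n_exp),
        is_control = FALSE,
        subpop = sp,
        phase = sample_phase(g, sp),
        spikein_kind = NA_character_,
        effect_group = g
      )
    }
    exp_ann <- list_rbind(rows)

    spike_rows <- list()
    for (g in groups) {
      nl <- cfg$spikein_low_quality_per_group
      nd <- cfg$spikein_doublet_per_group
      if (nl > 0) {
        sp <- sample_subpop(g, nl)
        spike_rows[[paste0(g, "_lq")]] <- tibble(
          group = g, donor = paste0(g, "_d1"), is_control = FALSE,
          subpop = sp, phase = sample_phase(g, sp),
          spikein_kind = "low_quality", effect_group = g
        )
      }
      if (nd > 0) {
        spike_rows[[paste0(g, "_db")]] <- tibble(
          group = rep(g, nd), donor = paste0(g, "_d1"), is_control = FALSE,
          subpop = NA_character_, phase = NA_character_,
          spikein_kind = "doublet", effect_group = g
        )
      }
    }
    spike_ann <- if (length(spike_rows)) list_rbind(spike_rows) else NULL

    ctrl_ann <- NULL
    if (n_controls > 0) {
      sp <- sample_subpop("NC", n_controls)
      ctrl_ann <- tibble(
        group = "NC", donor = "NC_d1", is_control = TRUE,
        subpop = sp, phase = sample_phase("NC", sp),
        spikein_kind = NA_character_,
        effect_group = "__baseline__"  # zero group effects by construction
      )
    }

    noncontrol <- bind_rows(exp_ann, spike_ann)
    slots <- cfg$plate_size - cfg$controls_per_plate
    plate_ids <- sprintf("p%02d", seq_len(n_plates))
    noncontrol$plate <- rep(plate_ids, each = max(slots, 1))[seq_len(nrow(noncontrol))]
    if (!is.null(ctrl_ann)) {
      ctrl_ann$plate <- rep(plate_ids, each = cfg$controls_per_plate)
    }
    ann <- bind_rows(noncontrol, ctrl_ann)
    ann$cell <- sprintf("cell%05d", seq_len(nrow(ann)))

    # -- depths
    ml <- cfg$depth_lognormal[["meanlog"]]; sl <- cfg$depth_lognormal[["sdlog"]]
    depth <- rlnorm(nrow(ann), ml, sl)
    lq <- !is.na(ann$spikein_kind) & ann$spikein_kind == "low_quality"
    depth[lq] <- cfg$low_quality_depth

    # -- counts
    size <- 1 / cfg$nb_dispersion
    counts <- matrix(0, nrow = cfg$n_genes, ncol = nrow(ann))
    eff_for <- function(eg) {
      if (eg == "__baseline__") {
        cfg$program_effects[0, , drop = FALSE]
      } else {
        cfg$program_effects[cfg$program_effects$group == eg, , drop = FALSE]
      }
    }
    is_doublet <- !is.na(ann$spikein_kind) & ann$spikein_kind == "doublet"
    key <- paste(ann$effect_group, ann$subpop, ann$phase, sep = "|")
    for (k in sort(unique(key[!is_doublet]))) {
      cells_k <- which(key == k & !is_doublet)
      first <- cells_k[1]
      prof <- .profile_for(abund, gs, cfg, eff_for(ann$effect_group[first]),
                           ann$subpop[first], ann$phase[first])
      mu <- outer(prof, depth[cells_k])
      counts[, cells_k] <- rnbinom(length(mu), size = size, mu = mu)
    }
    # doublets: sum of two independent cells at inflated depth
    for (i in which(is_doublet)) {
      g <- ann$effect_group[i]
      tot <- numeric(cfg$n_genes)
      for (p in 1:2) {
        sp <- sample_subpop(g, 1)
        ph <- sample_phase(g, sp)
        prof <- .profile_for(abund, gs, cfg, eff_for(g), sp, ph)
        d <- cfg$doublet_depth_factor * rlnorm(1, ml, sl)
        tot <- tot + rnbinom(cfg$n_genes, size = size, mu = prof * d)
      }
      counts[, i] <- tot
    }

    dimnames(counts) <- list(gs$genes, ann$cell)
    counts <- methods::as(Matrix::Matrix(t(counts), sparse = TRUE), "CsparseMatrix")

    planted <- cfg$program_effects
    planted_effects <- if (nrow(planted)) {
      list_rbind(purrr::map(seq_len(nrow(planted)), function(i) {
        tibble(group = planted$group[i], subpop = planted$subpop[i],
               set = planted$set[i], gene = gs$sets[[planted$set[i]]],
               log2fc = planted$log2fc[i])
      }))
    } else {
      tibble(group = character(), subpop = character(), set = character(),
             gene = character(), log2fc = numeric())
    }

    structure(list(
      counts = counts,
      annotations = ann[, c("cell", "group", "donor", "plate", "is_control")],
      truth = tibble(
        cell = ann$cell,
        subpop = ifelse(is.na(ann$spikein_kind), ann$subpop, NA_character_),
        phase = ifelse(is.na(ann$spikein_kind), ann$phase, NA_character_),
        spikein_kind = ann$spikein_kind
      ),
      gene_sets = gs$sets,
      planted_effects = planted_effects,
      config = cfg
    ), class = "synth_cohort")
  })
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> %d cells x %d genes; groups: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(names(x$config$group_sizes), collapse = ", ")))
  invisible(x)
}

# Minimal integer MatrixMarket writer (cells x genes written as genes x cells
# coordinate triplets, the layout downstream readers expect).
.write_mtx_integer <- function(m, path) {
  tm <- Matrix::t(m)  # genes x cells
  tm <- methods::as(tm, "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(tm), ncol(tm), length(tm@x))), con)
  if (length(tm@x)) {
    writeLines(sprintf("%d %d %d", tm@i + 1L, tm@j + 1L, as.integer(tm@x)), con)
  }
  invisible(path)
}

#' Write a cohort to disk as plain-text files
#'
#' Writes `matrix.mtx` (integer MatrixMarket, genes x cells), `genes.tsv`,
#' `barcodes.tsv`, `annotations.tsv`, `truth.tsv` and `programs.gmt` into
#' `dir`. The files round-trip bit-exactly through [read_cohort()].
#'
#' @param cohort A `synth_cohort` (or a list with `counts`, `annotations`,
#'   `truth`, `gene_sets`).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stopifnot(nrow(cohort$counts) == nrow(cohort$annotations))
  .write_mtx_integer(cohort$counts, file.path(dir, "matrix.mtx"))
  writeLines(as.character(colnames(cohort$counts) %||% character(0)),
             file.path(dir, "genes.tsv"))
  writeLines(as.character(rownames(cohort$counts) %||% character(0)),
             file.path(dir, "barcodes.tsv"))
  write.table(cohort$annotations, file.path(dir, "annotations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$truth, file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$gene_sets)) {
    write_gmt(cohort$gene_sets, file.path(dir, "programs.gmt"))
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the cohort files.
#' @return A list with `counts` (cells x genes sparse matrix), `annotations`,
#'   `truth` and `gene_sets` (if `programs.gmt` is present).
#' @export
read_cohort <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))  # genes x cells
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  counts <- methods::as(Matrix::t(m), "CsparseMatrix")
  dimnames(counts) <- list(cells, genes)
  ann <- as_tibble(read.table(file.path(dir, "annotations.tsv"),
                              sep = "\t", header = TRUE,
                              colClasses = "character"))
  if ("is_control" %in% names(ann)) ann$is_control <- ann$is_control == "TRUE"
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    as_tibble(read.table(truth_path, sep = "\t", header = TRUE,
                         colClasses = "character", na.strings = "NA"))
  } else {
    NULL
  }
  gmt_path <- file.path(dir, "programs.gmt")
  sets <- if (file.exists(gmt_path)) read_gmt(gmt_path) else NULL
  list(counts = counts, annotations = ann, truth = truth, gene_sets = sets)
}
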