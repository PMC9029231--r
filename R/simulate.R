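# Seeded synthetic-data generators. Every generator is a pure function of
# its arguments including the seed, so corpora, ortholog bundles and
# contrast tables are bit-reproducible and carry known ground truth.

#' Simulation specification
#'
#' Bundles the parameters of a synthetic promoter study: corpus sizes,
#' background model, planted motifs with per-kilobase rates in each arm,
#' cross-species conservation parameters, and the expression design.
#'
#' @param seed Master RNG seed.
#' @param n_test,n_control Promoters per arm.
#' @param promoter_length Promoter length (bp, <= 5000).
#' @param background Either a length-4 base-composition vector (A,C,G,T) for
#'   an i.i.d. background or a 4 x 4 order-1 transition matrix (rows =
#'   from-base). Default uniform.
#' @param plant List of planting instructions, each
#'   `list(pfm = <flex_pfm>, rate_test = <sites/kb>, rate_control =
#'   <sites/kb>)`. Per-promoter site counts are Poisson with mean
#'   `rate * length / 1000`; placements are non-overlapping.
#' @param species Pseudo-species names for ortholog bundles.
#' @param retention Probability that a planted site survives intact in an
#'   ortholog (otherwise it diverges like background), default 0.9.
#' @param divergence Background per-base substitution probability in the
#'   orthologs, default 0.4 (about the average neutral promoter divergence
#'   of mouse to rat, guinea pig, rabbit, human and marmoset).
#' @param deletion_rate Per-base deletion probability outside planted sites
#'   (introduces unaligned positions), default 0.
#' @return A `flex_sim_spec` list.
#' @export
sim_spec <- function(seed = 1L, n_test = 200L, n_control = 200L,
                     promoter_length = 1000L,
                     background = rep(0.25, 4), plant = list(),
                     species = c("rat", "guinea_pig", "rabbit", "human",
                                 "marmoset"),
                     retention = 0.9, divergence = 0.4,
                     deletion_rate = 0) {
  if (promoter_length > 5000) abort("promoter_length is capped at 5 kb")
  for (p in plant) {
    if (!inherits(p$pfm, "flex_pfm")) abort("each plant entry needs a $pfm")
    if (p$rate_test < 0 || p$rate_control < 0) abort("plant rates must be >= 0")
  }
  stopifnot(retention >= 0, retention <= 1,
            divergence >= 0, divergence <= 1,
            deletion_rate >= 0, deletion_rate < 1)
  structure(
    list(seed = as.integer(seed), n_test = as.integer(n_test),
         n_control = as.integer(n_control),
         promoter_length = as.integer(promoter_length),
         background = background, plant = plant, species = species,
         retention = retention, divergence = divergence,
         deletion_rate = deletion_rate),
    class = "flex_sim_spec"
  )
}

# sample an L bp background sequence (codes) from the spec's model
sample_background <- function(background, L) {
  if (is.matrix(background)) {
    P <- sweep(background, 1, rowSums(background), "/")
    if (max(abs(sweep(P, 2, colMeans(P)))) < 1e-12) {
      # all rows equal: order-0 shortcut
      return(sample.int(4L, L, replace = TRUE, prob = P[1, ]))
    }
    out <- integer(L)
    out[1] <- sample.int(4L, 1, prob = colMeans(P))
    for (i in 2:L) out[i] <- sample.int(4L, 1, prob = P[out[i - 1L], ])
    return(out)
  }
  sample.int(4L, L, replace = TRUE, prob = background / sum(background))
}

# sample a site (codes) column-wise from a PFM
sample_site <- function(pfm) {
  f <- sweep(pfm$counts, 2, colSums(pfm$counts), "/")
  vapply(seq_len(ncol(f)), function(i) sample.int(4L, 1, prob = f[, i]),
         integer(1))
}

#' Generate a synthetic promoter corpus with planted sites
#'
#' Background is sampled from the spec's composition model; planted motif
#' instances are sampled column-wise from each PFM, placed at random
#' non-overlapping offsets on a random strand, with per-promoter counts
#' Poisson at the arm's per-kilobase rate.
#'
#' @param spec A [sim_spec()].
#' @return A list with promoter-set tibbles `test` and `control` (gene ids
#'   `test_###` / `ctrl_###`) and `truth`, a tibble of planted-site
#'   coordinates (`arm`, `promoter_id`, `motif_id`, `start`, `end`
#'   0-based half-open, `strand`).
#' @export
gen_promoters <- function(spec) {
  stopifnot(inherits(spec, "flex_sim_spec"))
  withr::with_seed(spec$seed, {
    gen_arm <- function(n, prefix, arm) {
      ids <- sprintf("%s_%03d", prefix, seq_len(n))
      L <- spec$promoter_length
      truth <- list()
      seqs <- character(n)
      for (k in seq_len(n)) {
        codes <- sample_background(spec$background, L)
        occupied <- logical(L)
        for (p in spec$plant) {
          rate <- if (arm == "test") p$rate_test else p$rate_control
          n_sites <- rpois(1, rate * L / 1000)
          m <- ncol(p$pfm$counts)
          for (s in seq_len(n_sites)) {
            placed <- FALSE
            for (try in seq_len(200)) {
              start <- sample.int(L - m + 1L, 1) - 1L
              span <- (start + 1L):(start + m)
              if (any(occupied[span])) next
              site <- sample_site(p$pfm)
              strand <- sample(c("+", "-"), 1)
              if (strand == "-") site <- revcomp_codes(site)
              codes[span] <- site
              occupied[span] <- TRUE
              truth[[length(truth) + 1L]] <- tibble(
                arm = arm, promoter_id = ids[k], motif_id = p$pfm$motif_id,
                start = start, end = start + m, strand = strand
              )
              placed <- TRUE
              break
            }
            if (!placed) {
              abort("could not place a site without overlap; lower the rate")
            }
          }
        }
        seqs[k] <- decode_dna(codes)
      }
      empty <- tibble(arm = character(), promoter_id = character(),
                      motif_id = character(), start = integer(),
                      end = integer(), strand = character())
      list(set = promoter_set(ids, seqs, label = arm),
           truth = dplyr::bind_rows(empty, truth))
    }
    te <- gen_arm(spec$n_test, "test", "test")
    co <- gen_arm(spec$n_control, "ctrl", "control")
    list(test = te$set, control = co$set,
         truth = dplyr::bind_rows(te$truth, co$truth))
  })
}

#' Generate ortholog bundles for a synthetic corpus
#'
#' Each ortholog is a copy of the promoter with substitutions at the
#' background divergence rate; each planted site survives intact with the
#' retention probability (independently per species) and otherwise diverges
#' like background. Position maps are identity maps, minus any random
#' deletions outside planted sites.
#'
#' @param promoters A promoter-set tibble (typically
#'   `bind_rows(sim$test, sim$control)`).
#' @param truth The planted-site truth table from [gen_promoters()].
#' @param spec The [sim_spec()] (species, retention, divergence,
#'   deletion_rate).
#' @param seed RNG seed; defaults to `spec$seed + 1`.
#' @return A named list of [ortholog_bundle()] objects, one per species.
#' @export
gen_ortholog_bundles <- function(promoters, truth, spec,
                                 seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "flex_sim_spec"))
  site_pos <- split(truth, truth$promoter_id)
  withr::with_seed(seed, {
    bundles <- list()
    for (sp in spec$species) {
      seqs <- character(nrow(promoters))
      maps <- vector("list", nrow(promoters))
      for (k in seq_len(nrow(promoters))) {
        id <- promoters$gene_id[k]
        codes <- encode_dna(promoters$sequence[k])
        L <- length(codes)
        protect <- logical(L)
        tr <- site_pos[[id]]
        if (!is.null(tr)) {
          for (r in seq_len(nrow(tr))) {
            if (runif(1) < spec$retention) {
              protect[(tr$start[r] + 1L):tr$end[r]] <- TRUE
            }
          }
        }
        sub <- runif(L) < spec$divergence & !protect
        if (any(sub)) {
          shift <- sample.int(3L, sum(sub), replace = TRUE)
          codes[sub] <- ((codes[sub] - 1L + shift) %% 4L) + 1L
        }
        keep <- rep(TRUE, L)
        if (spec$deletion_rate > 0) {
          keep <- !(runif(L) < spec$deletion_rate & !protect)
        }
        ocodes <- codes[keep]
        mouse_pos <- which(keep) - 1L
        maps[[k]] <- stats::setNames(seq_along(ocodes) - 1L, mouse_pos)
        seqs[k] <- decode_dna(ocodes)
      }
      names(seqs) <- promoters$gene_id
      names(maps) <- promoters$gene_id
      bundles[[sp]] <- new_flex_bundle(sp, seqs, maps)
    }
    bundles
  })
}

#' Generate a synthetic expression contrast table with known classes
#'
#' Emulates a two-genotype (WT / KO) x {uninjured, d1, d4, d14} design.
#' Per-gene log2 expression is Gaussian around group means placed so each
#' planted class satisfies its regulatory-class pattern with margin;
#' contrasts are computed with two-sample Welch t-tests and
#' Benjamini-Hochberg correction per contrast and timepoint.
#'
#' Planted class labels: `JunUP_complete`, `JunUP_partial`, `JunDOWN`,
#' `AltUP_denovo`, `AltUP_enhanced`, `AltDOWN`, `none`, `control`
#' (`control` genes are unregulated, genotype-stable and highly expressed,
#' satisfying the control-promoter selection rule).
#'
#' @param class_counts Named integer vector of genes per planted label.
#' @param effect Log2 effect size of every informative contrast, default 2.
#' @param sd Residual log2 sd, default 0.25.
#' @param replicates Samples per group, default 4 (must be >= 2).
#' @param timepoints Injured timepoints, default `c("d1", "d4", "d14")`.
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline log2
#'   expression (control genes use baseline 9 +/- 0.3 so they clear the
#'   expression filter).
#' @param seed RNG seed.
#' @return A list with `contrasts` (tidy tibble: `gene`, `timepoint`,
#'   `wt_log2fc`, `wt_fdr`, `ko_vs_wt_log2fc`, `ko_vs_wt_fdr`, `ko_log2fc`,
#'   `ko_fdr`, `max_expression`) and `truth` (`gene`, `planted`,
#'   `true_class`, `true_dependence`).
#' @export
gen_contrast_table <- function(class_counts = c(JunUP_complete = 50,
                                                JunUP_partial = 50,
                                                JunDOWN = 50,
                                                AltUP_denovo = 50,
                                                AltUP_enhanced = 50,
                                                AltDOWN = 50,
                                                none = 100, control = 50),
                               effect = 2, sd = 0.25, replicates = 4,
                               timepoints = c("d1", "d4", "d14"),
                               baseline_mean = 8, baseline_sd = 1,
                               seed = 1L) {
  if (replicates < 2) abort("`replicates` must be >= 2")
  known <- c("JunUP_complete", "JunUP_partial", "JunDOWN", "AltUP_denovo",
             "AltUP_enhanced", "AltDOWN", "none", "control")
  if (!all(names(class_counts) %in% known)) {
    abort(paste("unknown class labels; use:", paste(known, collapse = ", ")))
  }
  # axotomy effects (delta over baseline) per genotype for each label
  deltas <- list(
    JunUP_complete = c(wt = 1, ko = 0), JunUP_partial = c(wt = 2, ko = 1),
    JunDOWN = c(wt = -1, ko = 0), AltUP_denovo = c(wt = 0, ko = 1),
    AltUP_enhanced = c(wt = 1, ko = 2), AltDOWN = c(wt = 0, ko = -1),
    none = c(wt = 0, ko = 0), control = c(wt = 0, ko = 0)
  )
  class_of <- list(
    JunUP_complete = c("JunUP", "complete"),
    JunUP_partial = c("JunUP", "partial"),
    JunDOWN = c("JunDOWN", NA), AltUP_denovo = c("AltUP", NA),
    AltUP_enhanced = c("AltUP", NA), AltDOWN = c("AltDOWN", NA),
    none = c("none", NA), control = c("none", NA)
  )
  withr::with_seed(seed, {
    planted <- rep(names(class_counts), class_counts)
    n_genes <- length(planted)
    gene <- sprintf("gene_%04d", seq_len(n_genes))
    baseline <- ifelse(planted == "control",
                       rnorm(n_genes, 9, 0.3),
                       rnorm(n_genes, baseline_mean, baseline_sd))
    rows <- list()
    max_expr <- rep(-Inf, n_genes)
    samp <- function(mean) rnorm(replicates, mean, sd)
    for (tp in timepoints) {
      wt0 <- lapply(baseline, samp)           # WT uninjured
      ko0 <- lapply(baseline, samp)           # KO uninjured
      d <- deltas[planted]
      wt1 <- lapply(seq_len(n_genes),
                    function(i) samp(baseline[i] + effect * d[[i]]["wt"]))
      ko1 <- lapply(seq_len(n_genes),
                    function(i) samp(baseline[i] + effect * d[[i]]["ko"]))
      tt <- function(x, y) {
        h <- t.test(x, y)
        c(mean(x) - mean(y), h$p.value)
      }
      wt_c <- t(vapply(seq_len(n_genes),
                       function(i) tt(wt1[[i]], wt0[[i]]), numeric(2)))
      kw_c <- t(vapply(seq_len(n_genes),
                       function(i) tt(ko1[[i]], wt1[[i]]), numeric(2)))
      ko_c <- t(vapply(seq_len(n_genes),
                       function(i) tt(ko1[[i]], ko0[[i]]), numeric(2)))
      max_expr <- pmax(max_expr,
                       vapply(seq_len(n_genes), function(i) {
                         max(wt0[[i]], ko0[[i]], wt1[[i]], ko1[[i]])
                       }, numeric(1)))
      rows[[tp]] <- tibble(
        gene = gene, timepoint = tp,
        wt_log2fc = wt_c[, 1], wt_fdr = benjamini_hochberg(wt_c[, 2]),
        ko_vs_wt_log2fc = kw_c[, 1],
        ko_vs_wt_fdr = benjamini_hochberg(kw_c[, 2]),
        ko_log2fc = ko_c[, 1], ko_fdr = benjamini_hochberg(ko_c[, 2])
      )
    }
    contrasts <- dplyr::bind_rows(rows)
    contrasts$max_expression <- max_expr[match(contrasts$gene, gene)]
    truth <- tibble(
      gene = gene, planted = planted,
      true_class = vapply(planted, function(p) class_of[[p]][1], character(1)),
      true_dependence = vapply(planted, function(p) class_of[[p]][2],
                               character(1))
    )
    list(contrasts = contrasts, truth = truth)
  })
}

#' Worked example fixture
#'
#' A small deterministic bundle used throughout the test-suite oracles:
#' three matrices (the AP1-like `TGACTCA`, its CRE-like single-base
#' central-insertion variant `TGACGTCA`, and a GC-box decoy), 20 test + 20
#' control promoters of 500 bp with AP1 planted at a higher rate in the
#' test arm, and two pseudo-species ortholog bundles.
#'
#' @param seed Fixed seed (change only to build variants).
#' @return A list: `pfms`, `test`, `control`, `truth`, `bundles`.
#' @export
worked_fixture <- function(seed = 20211028L) {
  pfms <- list(motif_ap1(), motif_cre(), motif_gcbox())
  spec <- sim_spec(
    seed = seed, n_test = 20, n_control = 20, promoter_length = 500,
    plant = list(
      list(pfm = pfms[[1]], rate_test = 1.0, rate_control = 0.2),
      list(pfm = pfms[[2]], rate_test = 0.4, rate_control = 0.4)
    ),
    species = c("spA", "spB"), retention = 0.9, divergence = 0.2
  )
  sim <- gen_promoters(spec)
  bundles <- gen_ortholog_bundles(dplyr::bind_rows(sim$test, sim$control),
                                  sim$truth, spec)
  list(pfms = pfms, test = sim$test, control = sim$control,
       truth = sim$truth, bundles = bundles, spec = spec)
}
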