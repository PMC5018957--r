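#' Read a pipeline configuration
#'
#' A configuration is a plain YAML file (or an equivalent R list) with the
#' components understood by [run_pipeline()]; see that help page.
#'
#' @param path YAML file path.
#' @return The configuration list.
#' @export
read_pipeline_config <- function(path) yaml::read_yaml(path)

#' Run the full analysis chain
#'
#' Stages, in dependency order: `simulate` (when `config$simulation` is
#' present) or loading of user-supplied call sets / depth tracks from
#' `config$input_dir`; per-accession `consensus`; optional `concordance`
#' against a second simulated technology; `matrix` (bi-allelic genotype
#' matrix); `tree`; `pca`; optional `admixture` K scan with Evanno table;
#' `winstats` (windowed haplotype diversity and pairwise F_ST per group);
#' `ld` (decay and blocks per group). Every stage writes plain-text
#' artifacts under `config$out_dir`, and the run finishes with a JSON
#' manifest recording stage parameters and the MD5 of every artifact. A
#' fixed `config$seed` makes the whole run byte-reproducible.
#'
#' Recognised configuration components:
#' * `out_dir` (required), `seed` (default 1);
#' * `simulation`: list with `n_chromosomes`, `chromosome_lengths`,
#'   `n_sites`, `groups` (data.frame-able list with name/n/F), optional
#'   `admixed`, `recomb_rate`, plus optional `profiles`
#'   (list of name/fn_rate/fp_rate/depth_lambda), `error_rate`;
#' * `input_dir`: directory of `<accession>.<caller>.vcf` plus
#'   `<accession>.bedgraph` files (used when `simulation` is absent;
#'   `accessions` and `callers` list what to load);
#' * `min_depth` (5), `min_alt_frac` (0.9), `max_third_allele_frac` (0.1),
#'   `reference_name` ("reference");
#' * `window_bp` (5e6);
#' * `admixture`: list with `k_range`, `n_runs`, `burnin`, `reps`;
#' * `ld`: list with `groups` (names), `max_dist`, `maf_min`,
#'   `bin_width`, `min_span_bp`;
#' * `concordance`: list with `profiles` for the second technology (and
#'   optional `error_rate`), compared per accession.
#'
#' @param config list or YAML path.
#' @return The manifest (also written to `out_dir/manifest.json`),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  min_depth <- config$min_depth %||% 5L
  min_alt_frac <- config$min_alt_frac %||% 0.90
  manifest <- list(seed = seed, stages = list())
  artifacts <- character(0)
  emit <- function(stage, params, files) {
    manifest$stages[[stage]] <<- list(params = params, files = files)
    artifacts <<- c(artifacts, files)
  }

  # --- stage: inputs (simulate or load) ----------------------------------
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    model <- population_model(
      n_chromosomes = sim$n_chromosomes %||% 2L,
      chromosome_lengths = unlist(sim$chromosome_lengths %||% 1e6),
      n_sites = sim$n_sites %||% 500L,
      groups = as.data.frame(sim$groups %||%
        list(name = c("oriental", "occidental"), n = c(8L, 8L),
             F = c(0.3, 0.3))),
      admixed = if (!is.null(sim$admixed)) as.data.frame(sim$admixed),
      recomb_rate = sim$recomb_rate %||% 2e-4,
      seed = seed)
    truth <- simulate_populations(model)
    profiles <- if (!is.null(sim$profiles))
      lapply(sim$profiles, function(p)
        caller_profile(p$name, p$fn_rate %||% 0, p$fp_rate %||% 0,
                       p$depth_lambda %||% 30))
    else default_caller_profiles()
    outputs <- simulate_caller_outputs(truth, profiles, seed = seed + 1L,
                                       error_rate = sim$error_rate %||% 0.01)
    sim_dir <- file.path(out_dir, "simulated")
    write_simulated_panel(truth, outputs, sim_dir)
    calls <- lapply(outputs, `[[`, "calls")
    depths <- lapply(outputs, `[[`, "depth")
    group_of <- truth$group_of
    chrom_lengths <- setNames(model$chromosome_lengths,
                              sprintf("chr%dH", seq_len(model$n_chromosomes)))
    emit("simulate", list(seed = seed, n_sites = model$n_sites),
         list.files(sim_dir, full.names = TRUE))
  } else {
    if (is.null(config$input_dir))
      stop("stage 'inputs': config needs either a 'simulation' block or ",
           "an 'input_dir'")
    acc <- config$accessions
    callers <- config$callers
    if (is.null(acc) || is.null(callers))
      stop("stage 'inputs': 'accessions' and 'callers' must list what to load")
    calls <- lapply(setNames(acc, acc), function(a)
      lapply(setNames(callers, callers), function(cl) {
        f <- file.path(config$input_dir, paste0(a, ".", cl, ".vcf"))
        if (!file.exists(f))
          stop("stage 'inputs': missing call file ", f)
        read_vcf(f, accession = a, caller = cl)
      }))
    depths <- lapply(setNames(acc, acc), function(a) {
      f <- file.path(config$input_dir, paste0(a, ".bedgraph"))
      if (!file.exists(f))
        stop("stage 'consensus': accession ", a, " has no depth track (",
             f, "); consensus filtering requires one")
      read_bedgraph(f, accession = a)
    })
    group_of <- unlist(config$groups_of) %||%
      setNames(rep("all", length(acc)), acc)
    chrom_lengths <- unlist(config$chrom_lengths)
    truth <- NULL
    emit("inputs", list(input_dir = config$input_dir), character(0))
  }
  groups <- split(names(group_of), group_of)

  # --- stage: consensus ---------------------------------------------------
  cons <- lapply(setNames(names(calls), names(calls)), function(a)
    consensus_calls(calls[[a]], depth = depths[[a]],
                    min_depth = min_depth, min_alt_frac = min_alt_frac))
  cons_sum <- do.call(rbind, lapply(cons, `[[`, "summary"))
  f_sum <- file.path(out_dir, "consensus_summary.tsv")
  write.table(cons_sum, f_sum, sep = "\t", quote = FALSE, row.names = FALSE)
  cons_dir <- file.path(out_dir, "consensus")
  dir.create(cons_dir, showWarnings = FALSE)
  for (a in names(cons))
    write_callset_vcf(cons[[a]]$consensus,
                      file.path(cons_dir, paste0(a, ".consensus.vcf")))
  emit("consensus",
       list(min_depth = min_depth, min_alt_frac = min_alt_frac),
       c(f_sum, list.files(cons_dir, full.names = TRUE)))

  # --- stage: concordance (optional, simulation only) ---------------------
  if (!is.null(config$concordance) && !is.null(truth)) {
    cc <- config$concordance
    profiles2 <- if (!is.null(cc$profiles))
      lapply(cc$profiles, function(p)
        caller_profile(p$name, p$fn_rate %||% 0, p$fp_rate %||% 0,
                       p$depth_lambda %||% 30))
    else default_caller_profiles(depth_lambda = 40)
    out2 <- simulate_caller_outputs(truth, profiles2, seed = seed + 2L,
                                    error_rate = cc$error_rate %||% 0.01)
    rows <- lapply(names(cons), function(a) {
      filt2 <- lapply(out2[[a]]$calls, filter_homozygous,
                      min_depth = min_depth, min_alt_frac = min_alt_frac)
      cons2 <- intersect_callers(filt2[[1]], filt2[[2]], filt2[[3]])
      raw2 <- do.call(rbind, lapply(out2[[a]]$calls, as.data.frame))
      raw2 <- raw2[!duplicated(paste(raw2$chrom, raw2$pos, raw2$alt)), ]
      res <- classify_concordance(cons[[a]]$consensus, cons2, filt2, raw2)
      data.frame(accession = a, t(res$counts), total = res$total)
    })
    conc <- do.call(rbind, rows)
    f_conc <- file.path(out_dir, "concordance.tsv")
    write.table(conc, f_conc, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("concordance", list(seed = seed + 2L), f_conc)
  }

  # --- stage: matrix ------------------------------------------------------
  M <- build_biallelic_matrix(
    lapply(cons, `[[`, "consensus"), depths, min_depth = min_depth,
    max_third_allele_frac = config$max_third_allele_frac %||% 0.10,
    reference_name = config$reference_name %||% "reference")
  f_mat <- file.path(out_dir, "biallelic_matrix.vcf")
  f_mat_tsv <- file.path(out_dir, "biallelic_matrix.tsv")
  write_matrix_vcf(M, f_mat)
  write_matrix_tsv(M, f_mat_tsv)
  idm <- pairwise_identity(M)
  f_id <- file.path(out_dir, "pairwise_identity.tsv")
  write.table(round(idm, 6), f_id, sep = "\t", quote = FALSE)
  emit("matrix", list(n_sites = ncol(M$G)), c(f_mat, f_mat_tsv, f_id))

  # --- stage: tree + pca --------------------------------------------------
  tree <- nj_tree(M)
  f_tree <- file.path(out_dir, "nj_tree.nwk")
  write_newick(tree, f_tree)
  pca <- run_pca(M)
  f_pca <- file.path(out_dir, "pca_scores.tsv")
  write.table(round(cbind(pca$scores,
                          eigenvalue = pca$eigenvalues[
                            seq_len(ncol(pca$scores))]), 6),
              f_pca, sep = "\t", quote = FALSE)
  emit("tree_pca", list(), c(f_tree, f_pca))

  # --- stage: admixture (optional) ---------------------------------------
  if (!is.null(config$admixture)) {
    ad <- config$admixture
    drop_ref <- setdiff(rownames(M$G), config$reference_name %||% "reference")
    Mad <- list(G = M$G[drop_ref, , drop = FALSE],
                sites = M$sites)
    class(Mad) <- "biallelic_matrix"
    scan <- admixture_scan(Mad, k_range = ad$k_range %||% 1:4,
                           n_runs = ad$n_runs %||% 3L,
                           seed = seed + 3L,
                           burnin = ad$burnin %||% 500L,
                           reps = ad$reps %||% 2000L)
    dk <- evanno_delta_k(scan$L)
    f_dk <- file.path(out_dir, "evanno_delta_k.tsv")
    write.table(dk, f_dk, sep = "\t", quote = FALSE, row.names = FALSE)
    k_best <- dk$K[which.max(dk$delta_K)]
    Qb <- scan$fits[[as.character(k_best)]][[1]]$Q
    f_q <- file.path(out_dir, sprintf("ancestry_Q_K%d.tsv", k_best))
    write.table(round(Qb, 6), f_q, sep = "\t", quote = FALSE)
    emit("admixture", list(k_range = ad$k_range %||% 1:4,
                           burnin = ad$burnin %||% 500L,
                           reps = ad$reps %||% 2000L, k_best = k_best),
         c(f_dk, f_q))
  }

  # --- stage: windowed statistics ----------------------------------------
  w <- config$window_bp %||% 5e6
  windows <- make_windows(chrom_lengths, w = w)
  grp_ok <- groups[lengths(groups) >= 2]
  if (length(grp_ok) >= 2) {
    ds <- diversity_summary(M, grp_ok, windows)
    f_hd <- file.path(out_dir, "windowed_hd.tsv")
    write.table(ds$hd, f_hd, sep = "\t", quote = FALSE, row.names = FALSE)
    f_fst <- file.path(out_dir, "fst_pairs.tsv")
    write.table(ds$fst, f_fst, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("winstats", list(window_bp = w), c(f_hd, f_fst))
  }

  # --- stage: LD ----------------------------------------------------------
  ld_cfg <- config$ld %||% list()
  ld_groups <- ld_cfg$groups %||% names(grp_ok)
  ld_rows <- list()
  for (g in ld_groups) {
    members <- if (g == "all") rownames(M$G) else groups[[g]]
    if (length(members) < 4L) next
    pairs <- pairwise_ld(M, members,
                         max_dist = ld_cfg$max_dist %||% 5e5,
                         maf_min = ld_cfg$maf_min %||% 0.05)
    if (!nrow(pairs)) next
    dec <- ld_decay(pairs, bin_width = ld_cfg$bin_width %||% 1000)
    ld_rows[[g]] <- cbind(group = g, dec$bins)
  }
  if (length(ld_rows)) {
    f_ld <- file.path(out_dir, "ld_decay.tsv")
    write.table(do.call(rbind, ld_rows), f_ld, sep = "\t", quote = FALSE,
                row.names = FALSE)
    emit("ld", list(max_dist = ld_cfg$max_dist %||% 5e5), f_ld)
  }

  # --- manifest -----------------------------------------------------------
  rel <- substring(artifacts, nchar(out_dir) + 2L)
  manifest$artifacts <- lapply(setNames(artifacts, rel),
                               function(f) unname(tools::md5sum(f)))
  f_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
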