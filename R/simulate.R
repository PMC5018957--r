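#' Describe a structured population to simulate
#'
#' The generator draws, for each segregating site, an ancestral allele
#' frequency p ~ Uniform(0.05, 0.95) and per-group frequencies from the
#' Balding-Nichols distribution Beta(p(1-F)/F, (1-p)(1-F)/F), which has mean
#' p and divergence parameter F equal to the expected Hudson F_ST of the
#' group against the ancestral pool (F = 0 is a point mass at p). Accessions
#' are inbred: one allele per site. Intra-chromosomal linkage comes from a
#' mosaic-donor model: walking along a chromosome, each accession carries a
#' current "donor" group whose frequency generates the allele, and the donor
#' is re-drawn from the accession's ancestry proportions with probability
#' 1 - exp(-recomb_rate * distance) between adjacent sites. Pure accessions
#' keep their own group as donor throughout, admixed accessions switch, so
#' admixture linkage decays with physical distance.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_lengths lengths in bp (recycled to `n_chromosomes`).
#' @param n_sites segregating sites per chromosome.
#' @param groups `data.frame` with columns `name`, `n`, `F`: group name,
#'   number of pure accessions, divergence F in `[0, 1)`.
#' @param admixed optional `data.frame` with column `name` plus one column
#'   per group giving ancestry proportions (rows sum to 1).
#' @param recomb_rate per-bp donor-switch rate c >= 0; the expected
#'   switch distance is 1/c bp.
#' @param seed integer seed making the whole simulation deterministic.
#' @return Object of class `population_model`.
#' @export
population_model <- function(n_chromosomes = 2L,
                             chromosome_lengths = 1e6,
                             n_sites = 1000L,
                             groups = data.frame(
                               name = c("oriental", "occidental"),
                               n = c(10L, 10L),
                               F = c(0.3, 0.3)),
                             admixed = NULL,
                             recomb_rate = 2e-4,
                             seed = 1L) {
  chromosome_lengths <- rep_len(as.numeric(chromosome_lengths),
                                n_chromosomes)
  stopifnot(is.data.frame(groups),
            all(c("name", "n", "F") %in% names(groups)))
  if (any(groups$F < 0) || any(groups$F >= 1))
    stop("group divergence F must lie in [0, 1); F = 1 is degenerate")
  if (any(chromosome_lengths < n_sites))
    stop("chromosome_lengths must be >= n_sites so positions are distinct")
  if (recomb_rate < 0) stop("recomb_rate must be >= 0")
  nm <- as.character(groups$name)
  if (!is.null(admixed)) {
    stopifnot(is.data.frame(admixed), "name" %in% names(admixed),
              all(nm %in% names(admixed)))
    w <- as.matrix(admixed[, nm, drop = FALSE])
    if (any(abs(rowSums(w) - 1) > 1e-9))
      stop("ancestry proportions of each admixed accession must sum to 1")
  }
  acc <- c(unlist(lapply(seq_len(nrow(groups)), function(i)
    sprintf("%s_%02d", nm[i], seq_len(groups$n[i])))),
    if (!is.null(admixed)) as.character(admixed$name))
  if (anyDuplicated(acc)) stop("duplicate accession names")
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chromosome_lengths = chromosome_lengths,
                 n_sites = as.integer(n_sites),
                 groups = groups, admixed = admixed,
                 recomb_rate = recomb_rate, seed = as.integer(seed)),
            class = "population_model")
}

#' Simulate true genotypes for a structured inbred panel
#'
#' See [population_model()] for the generative model.
#'
#' @param model a [population_model()].
#' @return Object of class `true_genotypes`: a list with
#'   * `sites`: `data.frame(chrom, pos, ref, alt)`, (chrom, pos)-sorted;
#'   * `G`: accessions x sites binary matrix (1 = alternative allele);
#'   * `group_of`: named character vector, accession -> group (admixed
#'     accessions are labelled `"admixed"`);
#'   * `freq`: groups x sites matrix of the drawn group frequencies;
#'   * `model`: the input model.
#' @export
simulate_populations <- function(model) {
  stopifnot(inherits(model, "population_model"))
  set.seed(model$seed)
  gnames <- as.character(model$groups$name)
  nG <- length(gnames)
  bases <- c("A", "C", "G", "T")

  sites <- do.call(rbind, lapply(seq_len(model$n_chromosomes), function(ci) {
    pos <- sort(sample.int(model$chromosome_lengths[ci], model$n_sites))
    data.frame(chrom = sprintf("chr%dH", ci), pos = pos,
               stringsAsFactors = FALSE)
  }))
  S <- nrow(sites)
  sites$ref <- sample(bases, S, replace = TRUE)
  sites$alt <- vapply(sites$ref,
                      function(r) sample(setdiff(bases, r), 1L), "")

  p_anc <- runif(S, 0.05, 0.95)
  freq <- matrix(NA_real_, nG, S, dimnames = list(gnames, NULL))
  for (g in seq_len(nG)) {
    F <- model$groups$F[g]
    freq[g, ] <- if (F == 0) p_anc else
      rbeta(S, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
  }

  # accession ancestry proportions over groups
  pure <- do.call(rbind, lapply(seq_len(nG), function(g) {
    n <- model$groups$n[g]
    if (n == 0L) return(NULL)
    w <- matrix(0, n, nG); w[, g] <- 1
    rownames(w) <- sprintf("%s_%02d", gnames[g], seq_len(n))
    w
  }))
  adm <- if (!is.null(model$admixed)) {
    w <- as.matrix(model$admixed[, gnames, drop = FALSE])
    rownames(w) <- as.character(model$admixed$name)
    w
  }
  W <- rbind(pure, adm)
  acc <- rownames(W)
  nA <- length(acc)
  is_adm <- rep(c(FALSE, TRUE), c(NROW(pure), NROW(adm)))

  G <- matrix(0L, nA, S, dimnames = list(acc, NULL))
  c_rate <- model$recomb_rate
  for (ci in seq_len(model$n_chromosomes)) {
    idx <- which(sites$chrom == sprintf("chr%dH", ci))
    pos <- sites$pos[idx]
    p_switch <- 1 - exp(-c_rate * diff(pos))
    for (a in seq_len(nA)) {
      if (!is_adm[a]) {
        donor <- rep.int(which(W[a, ] == 1), length(idx))
      } else {
        donor <- integer(length(idx))
        donor[1] <- sample.int(nG, 1L, prob = W[a, ])
        if (length(idx) > 1L) {
          switch <- runif(length(idx) - 1L) < p_switch
          for (s in 2L:length(idx)) {
            donor[s] <- if (switch[s - 1L])
              sample.int(nG, 1L, prob = W[a, ]) else donor[s - 1L]
          }
        }
      }
      G[a, idx] <- as.integer(runif(length(idx)) < freq[cbind(donor, idx)])
    }
  }

  group_of <- setNames(ifelse(is_adm, "admixed",
                              gnames[max.col(W, ties.method = "first")]),
                       acc)
  structure(list(sites = sites, G = G, group_of = group_of,
                 freq = freq, model = model),
            class = "true_genotypes")
}

#' @export
print.true_genotypes <- function(x, ...) {
  cat(sprintf("<true_genotypes> %d accession(s) x %d site(s) on %d chromosome(s)\n",
              nrow(x$G), ncol(x$G), length(unique(x$sites$chrom))))
  cat("groups:", paste(sprintf("%s=%d", names(table(x$group_of)),
                               table(x$group_of)), collapse = ", "), "\n")
  invisible(x)
}

#' Describe a variant caller's error profile
#'
#' @param name caller name.
#' @param fn_rate probability a true SNP is missed (false negative).
#' @param fp_rate expected false calls per Mb of covered sequence.
#' @param depth_lambda mean of the per-site Poisson depth distribution.
#' @return Object of class `caller_profile`.
#' @export
caller_profile <- function(name, fn_rate = 0, fp_rate = 0,
                           depth_lambda = 30) {
  stopifnot(fn_rate >= 0, fn_rate <= 1, fp_rate >= 0, depth_lambda > 0)
  structure(list(name = name, fn_rate = fn_rate, fp_rate = fp_rate,
                 depth_lambda = depth_lambda), class = "caller_profile")
}

#' Default three-caller profile set
#'
#' Mirrors a typical multi-caller design (freebayes, glfMultiples,
#' samtools) with mild, caller-specific error rates.
#' @param depth_lambda shared mean depth.
#' @return List of three [caller_profile()]s.
#' @export
default_caller_profiles <- function(depth_lambda = 30) {
  list(caller_profile("freebayes", 0.05, 2, depth_lambda),
       caller_profile("glfMultiples", 0.02, 10, depth_lambda),
       caller_profile("samtools", 0.04, 5, depth_lambda))
}

#' Simulate per-caller call sets and depth tracks from true genotypes
#'
#' One depth track is drawn per accession (Poisson depths, piecewise
#' constant over `tile` bp, mean equal to the average of the three callers'
#' `depth_lambda`) and shared by the accession's three callers. Each caller
#' reports each true alternative-allele site with probability
#' `1 - fn_rate`, with `alt_reads ~ Binomial(depth, 1 - error_rate)`;
#' false-positive calls are placed uniformly over covered non-SNP positions
#' at `fp_rate` per Mb with the same confident alt-read model, so they pass
#' per-caller filters and are removed only by the cross-caller intersection.
#'
#' @param truth a [simulate_populations()] result.
#' @param profiles list of exactly three [caller_profile()]s.
#' @param seed integer seed.
#' @param error_rate per-read sequencing error rate (default 0.01).
#' @param tile width in bp of the constant-depth tiles of the depth track.
#' @return Named list per accession, each with elements `calls` (named list
#'   of three [callset()]s) and `depth` (a [depth_track()]).
#' @export
simulate_caller_outputs <- function(truth, profiles, seed = 1L,
                                    error_rate = 0.01, tile = 200L) {
  stopifnot(inherits(truth, "true_genotypes"), length(profiles) == 3L)
  genome_mb <- sum(truth$model$chromosome_lengths) / 1e6
  for (pr in profiles) {
    stopifnot(inherits(pr, "caller_profile"))
    n_true <- mean(rowSums(truth$G))
    if (n_true > 0 && pr$fp_rate * genome_mb > 0.5 * n_true)
      stop("profile '", pr$name, "' would produce more than 0.5 false ",
           "calls per true call; lower fp_rate")
  }
  set.seed(seed)
  lambda <- mean(vapply(profiles, `[[`, 0, "depth_lambda"))
  chroms <- sprintf("chr%dH", seq_len(truth$model$n_chromosomes))
  lens <- truth$model$chromosome_lengths
  acc <- rownames(truth$G)
  out <- vector("list", length(acc))
  names(out) <- acc
  for (a in seq_along(acc)) {
    # shared piecewise-constant depth track
    iv <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
      starts <- seq(0L, lens[ci] - 1L, by = tile)
      ends <- pmin(starts + tile, lens[ci])
      data.frame(chrom = chroms[ci], start = as.integer(starts),
                 end = as.integer(ends),
                 depth = rpois(length(starts), lambda),
                 stringsAsFactors = FALSE)
    }))
    track <- depth_track(iv, accession = acc[a])
    alt_idx <- which(truth$G[a, ] == 1L)
    site_depth <- depth_at(track, truth$sites$chrom[alt_idx],
                           truth$sites$pos[alt_idx])
    calls <- vector("list", 3L)
    names(calls) <- vapply(profiles, `[[`, "", "name")
    for (k in 1:3) {
      pr <- profiles[[k]]
      keep <- runif(length(alt_idx)) >= pr$fn_rate & site_depth > 0L
      ti <- alt_idx[keep]
      td <- site_depth[keep]
      ta <- rbinom(length(ti), td, 1 - error_rate)
      cs <- data.frame(chrom = truth$sites$chrom[ti],
                       pos = truth$sites$pos[ti],
                       ref = truth$sites$ref[ti],
                       alt = truth$sites$alt[ti],
                       alt_reads = ta, depth = td,
                       stringsAsFactors = FALSE)
      n_fp <- rpois(1L, pr$fp_rate * genome_mb)
      if (n_fp > 0L) {
        fp <- fp_positions(n_fp, chroms, lens, truth$sites, track)
        if (nrow(fp)) {
          fp$alt_reads <- rbinom(nrow(fp), fp$depth, 1 - error_rate)
          cs <- rbind(cs, fp[, names(cs)])
        }
      }
      cs <- cs[cs$depth > 0L, , drop = FALSE]
      calls[[k]] <- callset(cs$chrom, cs$pos, cs$ref, cs$alt,
                            cs$alt_reads, cs$depth,
                            accession = acc[a], caller = pr$name)
    }
    out[[a]] <- list(calls = calls, depth = track)
  }
  out
}

# uniform false-positive positions over covered, non-SNP positions
fp_positions <- function(n_fp, chroms, lens, sites, track) {
  bases <- c("A", "C", "G", "T")
  ci <- sample.int(length(chroms), n_fp, replace = TRUE,
                   prob = lens / sum(lens))
  pos <- vapply(ci, function(i) sample.int(lens[i], 1L), 0L)
  chrom <- chroms[ci]
  key <- paste(chrom, pos)
  dup <- duplicated(key) | key %in% paste(sites$chrom, sites$pos)
  chrom <- chrom[!dup]; pos <- pos[!dup]
  d <- depth_at(track, chrom, pos)
  cov <- d > 0L
  chrom <- chrom[cov]; pos <- pos[cov]; d <- d[cov]
  if (!length(pos))
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      depth = integer(), stringsAsFactors = FALSE))
  ref <- sample(bases, length(pos), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, depth = d,
             stringsAsFactors = FALSE)
}

#' Write a simulated panel to disk
#'
#' Writes, under `dir`: one VCF per accession and caller
#' (`<accession>.<caller>.vcf`), one BedGraph depth track per accession
#' (`<accession>.bedgraph`), and a truth table
#' `truth.tsv` (accession, chrom, pos, ref, alt, genotype, group).
#'
#' @param truth a [simulate_populations()] result.
#' @param outputs a [simulate_caller_outputs()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_panel <- function(truth, outputs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (a in names(outputs)) {
    for (cl in outputs[[a]]$calls)
      write_callset_vcf(cl, file.path(dir, paste0(
        a, ".", attr(cl, "caller"), ".vcf")))
    write_bedgraph(outputs[[a]]$depth, file.path(dir, paste0(a, ".bedgraph")))
  }
  tt <- do.call(rbind, lapply(rownames(truth$G), function(a) {
    data.frame(accession = a, chrom = truth$sites$chrom,
               pos = truth$sites$pos, ref = truth$sites$ref,
               alt = truth$sites$alt, genotype = truth$G[a, ],
               group = truth$group_of[[a]], stringsAsFactors = FALSE)
  }))
  write.table(tt, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Example three-group panel design
#'
#' A compact analogue of a domesticated-crop diversity panel: two diverged
#' pure sub-populations ("oriental" and "occidental", 10 accessions each,
#' Balding-Nichols F = 0.3) plus a "marginal" group of 8 admixed
#' accessions whose oriental ancestry ranges evenly from 0.25 to 0.75.
#' Seven chromosomes of 30 Mb carry 60 segregating sites each, so a 5-Mb
#' window holds about ten sites — sparse enough that window haplotypes
#' recur within groups, which is the regime in which haplotype diversity
#' is informative for this generator (it has no within-group linkage; see
#' the package vignette).
#'
#' @param seed integer seed.
#' @param n_sites segregating sites per chromosome (default 60).
#' @return A [population_model()].
#' @export
demo_three_group_model <- function(seed = 1L, n_sites = 60L) {
  adm <- data.frame(name = sprintf("marginal_%02d", 1:8),
                    oriental = seq(0.25, 0.75, length.out = 8))
  adm$occidental <- 1 - adm$oriental
  population_model(
    n_chromosomes = 7L, chromosome_lengths = 30e6, n_sites = n_sites,
    groups = data.frame(name = c("oriental", "occidental"),
                        n = c(10L, 10L), F = c(0.3, 0.3)),
    admixed = adm, recomb_rate = 2e-4, seed = seed)
}

#' Group assignments of a simulated panel
#'
#' @param truth a [simulate_populations()] result.
#' @return Named list of accession-name vectors, one per group.
#' @export
panel_groups <- function(truth) split(names(truth$group_of), truth$group_of)
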