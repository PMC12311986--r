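#' Default pipeline configuration
#'
#' One nested list drives every stage; [read_pipeline_config()] merges a
#' YAML file over these defaults and rejects unknown keys. The demo scale
#' (small populations, short contigs, scaled-up mutation rate) runs the
#' full pipeline in well under a minute while leaving every stage with
#' enough signal to summarize.
#'
#' @return nested named list.
#' @export
pipeline_config <- function() {
  list(
    seed = 1,
    log_level = "info",
    inputs = list(vcf = NULL, popmap = NULL, annotation = NULL, gff = NULL),
    simulate = list(n_anc = 200, n_x = 30, n_y = 120, t_split = 100,
                    mu = 1e-6, L = 5e4, n_chrom = 2,
                    sample_x = 8, sample_y = 8,
                    selfing_x = 0.2, selfing_y = 0, recomb = 1e-7),
    annotate = list(synonymous = 0.5, tolerated_nonsynonymous = 0.3,
                    deleterious = 0.2),
    filter = list(max_missing = 0.8, max_obs_het = 0.6,
                  drop_indels = TRUE, biallelic_only = TRUE),
    polarize = list(outgroup = "outgroup"),
    rxy = list(pop_x = "popX", pop_y = "popY", n_blocks = 20),
    pi = list(window_bp = 10000),
    roh = list(genome_length_bp = NULL),
    ld = list(max_dist_bp = 20000, bin_bp = 1000, maf_min = 0.05,
              max_missing = 0.1),
    scan = list(window_bp = 10000, quantile = 0.01, min_ehh = 0.05),
    tree = list(n_bootstrap = 25),
    pca = list(n_components = 2))
}

merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    full <- if (path == "") k else paste0(path, ".", k)
    if (!k %in% names(defaults))
      stop("unknown configuration key: ", full)
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      defaults[[k]] <- merge_config(defaults[[k]], as.list(user[[k]]), full)
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Read a YAML pipeline configuration
#' @param path YAML file with (a subset of) the sections of
#'   [pipeline_config()]; unknown keys are rejected.
#' @return merged configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  merge_config(pipeline_config(), yaml::read_yaml(path))
}

pipe_log <- function(cfg, stage, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message("[", stage, "] ", ...)
}

#' Run the full demonstration pipeline
#'
#' simulate -> filter -> polarize -> load/R_xy -> diversity (pi, het,
#' region het) -> ROH/F_ROH -> LD decay -> scans (Tajima's D, FST,
#' XP-EHH) -> candidate intersection -> NJ tree + PCA, writing per-stage
#' TSVs and a consolidated `report.txt` into `out_dir`. If
#' `config$inputs$vcf` is set, that VCF (with its population map) is used
#' instead of simulating.
#'
#' @param config a [pipeline_config()]-shaped list.
#' @param out_dir output directory.
#' @param seed overrides `config$seed` when given.
#' @return invisibly, a named list of all stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = NULL) {
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  res <- list()
  report <- c(paste0("popgenpipe pipeline report (seed ", config$seed,
                     ", config ", config_hash(config), ")"), "")
  add <- function(title, df) {
    report <<- c(report, paste0("== ", title, " =="),
                 utils::capture.output(print(df)), "")
  }
  tsv <- function(x, name) write_tsv(x, file.path(out_dir, name),
                                     params = config, seed = config$seed)

  if (is.null(config$inputs$vcf)) {
    pipe_log(config, "simulate", "forward Wright-Fisher simulation")
    sim <- simulate_two_pops(do.call(sim_config,
      c(config$simulate, list(seed = config$seed))))
    write_sim_outputs(sim, out_dir)
    gm <- sim$genotypes
    res$sim_truth <- sim$truth
  } else {
    pipe_log(config, "input", "reading ", config$inputs$vcf)
    gm <- read_vcf(config$inputs$vcf,
                   population_map = read_population_map(config$inputs$popmap))
  }
  add("input genotypes", data.frame(
    samples = n_samples(gm), sites = n_sites(gm),
    invariant = sum(is_invariant(gm))))

  pipe_log(config, "filter", "site/genotype filters")
  fl <- apply_filters(gm, do.call(filter_config, config$filter))
  gm <- fl$genotypes
  tsv(fl$report, "filter_report.tsv")
  add("filtering", fl$report)

  pipe_log(config, "polarize", "outgroup ", config$polarize$outgroup)
  pm <- infer_ancestral(gm, config$polarize$outgroup)
  tsv(pm$dropped, "polarize_dropped.tsv")
  add("polarization", data.frame(
    polarized = ncol(pm$derived_dosage), dropped = nrow(pm$dropped)))

  ann <- if (!is.null(config$inputs$annotation))
    read_annotation(config$inputs$annotation)
  else {
    cats <- sample(c(names(config$annotate), "unannotated"),
                   ncol(pm$derived_dosage), replace = TRUE,
                   prob = c(unlist(config$annotate),
                            max(0, 1 - sum(unlist(config$annotate)))))
    classify_variants(data.frame(
      chrom = pm$base$chrom, pos = pm$base$pos, ref = pm$base$ref,
      alt = pm$base$alt, category = cats, stringsAsFactors = FALSE))
  }
  pipe_log(config, "load", "additive load and R_xy")
  loads <- additive_load(pm, ann)
  tsv(loads, "additive_load.tsv")
  add("additive load (head)", utils::head(loads, 8))
  rx <- lapply(setdiff(unique(ann$category), "unannotated"), function(cat)
    tryCatch(rxy(pm, ann, config$rxy$pop_x, config$rxy$pop_y, cat,
                 n_blocks = config$rxy$n_blocks),
             error = function(e) NULL))
  rx <- rx[!vapply(rx, is.null, logical(1))]
  rx_df <- do.call(rbind, lapply(rx, function(r) data.frame(
    category = r$category, freq_x = r$freq_x, freq_y = r$freq_y,
    rxy = r$rxy, ci_low = r$ci_low, ci_high = r$ci_high,
    n_sites = r$n_sites)))
  tsv(rx_df, "rxy.tsv")
  add("R_xy", rx_df)
  res$rxy <- rx

  pipe_log(config, "diversity", "windowed pi and heterozygosity")
  ingroup <- subset_samples(gm, setdiff(gm$samples, config$polarize$outgroup))
  pi_x <- windowed_pi(ingroup, "popX", config$pi$window_bp)
  pi_y <- windowed_pi(ingroup, "popY", config$pi$window_bp)
  tsv(pi_x, "pi_popX.tsv"); tsv(pi_y, "pi_popY.tsv")
  add("genome-wide pi", data.frame(
    population = c("popX", "popY"),
    pi = c(genome_pi(pi_x), genome_pi(pi_y))))
  het <- individual_heterozygosity(ingroup)
  tsv(het, "heterozygosity.tsv")
  add("heterozygosity", het)
  gff_path <- if (!is.null(config$inputs$gff)) config$inputs$gff
              else file.path(out_dir, "annotation.gff3")
  if (file.exists(gff_path)) {
    rh <- region_stratified_het(ingroup, gff_path)
    tsv(rh, "region_het.tsv")
    add("region-stratified het (head)", utils::head(rh, 8))
    res$region_het <- rh
  }

  pipe_log(config, "roh", "runs of homozygosity")
  segs <- detect_roh(ingroup)
  genome_len <- config$roh$genome_length_bp
  if (is.null(genome_len))
    genome_len <- sum(ingroup$contig_lengths, na.rm = TRUE)
  fr <- froh(segs, genome_len, samples = ingroup$samples)
  tsv(segs, "roh_segments.tsv"); tsv(fr, "froh.tsv")
  add("F_ROH", fr)

  pipe_log(config, "ld", "LD decay")
  ldc <- suppressWarnings(ld_decay(ingroup, "popY",
    max_dist_bp = config$ld$max_dist_bp, bin_bp = config$ld$bin_bp,
    maf_min = config$ld$maf_min, max_missing = config$ld$max_missing))
  tsv(ldc, "ld_decay_popY.tsv")
  add("LD decay (first bins)", utils::head(as.data.frame(ldc), 5))

  pipe_log(config, "scan", "Tajima's D, FST, XP-EHH")
  td <- tajimas_d(ingroup, "popX", config$scan$window_bp)
  fst <- wc_fst(ingroup, "popX", "popY", config$scan$window_bp)
  tsv(td, "tajimas_d_popX.tsv"); tsv(fst, "fst.tsv")
  add("Tajima's D (head)", utils::head(as.data.frame(td), 5))
  add("FST (head)", utils::head(as.data.frame(fst), 5))
  xp <- if (!is.null(ingroup$hap1))
    xpehh(ingroup, "popX", "popY", min_ehh = config$scan$min_ehh,
          window_bp = config$scan$window_bp) else NULL
  if (!is.null(xp)) {
    tsv(xp, "xpehh.tsv")
    add("XP-EHH (head)", utils::head(as.data.frame(xp), 5))
    cand <- top_intersect(fst, xp, quantile = config$scan$quantile,
                          gene_annotation = if (file.exists(gff_path))
                            read_gff_regions(gff_path) else NULL)
    tsv(cand$intersection, "candidate_regions.tsv")
    add("candidate regions", cand$intersection)
    add("candidate genes", data.frame(gene = if (length(cand$genes))
      cand$genes else "(none)"))
    res$candidates <- cand
  }

  pipe_log(config, "tree", "p-distance NJ tree and PCA")
  bs <- bootstrap_support(ingroup, n_reps = config$tree$n_bootstrap,
                          seed = config$seed)
  ape::write.tree(bs, file.path(out_dir, "nj_tree.nwk"))
  add("NJ tree", data.frame(newick = ape::write.tree(bs)))
  pc <- pca_genotypes(ingroup, n_components = config$pca$n_components)
  tsv(data.frame(sample = rownames(pc$scores), pc$scores), "pca_scores.tsv")
  add("PCA explained variance",
      data.frame(component = seq_along(pc$explained[1:config$pca$n_components]),
                 fraction = pc$explained[1:config$pca$n_components]))

  writeLines(report, file.path(out_dir, "report.txt"))
  res <- c(res, list(genotypes = gm, polarized = pm, loads = loads,
                     pi = list(popX = pi_x, popY = pi_y), het = het,
                     roh = segs, froh = fr, ld = ldc,
                     tajimas_d = td, fst = fst, xpehh = xp,
                     tree = bs, pca = pc))
  invisible(res)
}

#' Command-line entry point
#'
#' In-process implementation of the `popgenpipe` command; the installed
#' script `inst/scripts/popgenpipe` is a thin wrapper around it. Global
#' flags: `--config <yaml>`, `--seed <int>`, `--out-dir <dir>`,
#' `--log-level <info|quiet>`. Subcommands: `simulate` (write simulated
#' inputs) and `paper-pipeline` (alias `pipeline`; the full run of
#' [run_pipeline()]); the per-stage analyses are reachable through the
#' pipeline or the package functions.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status: 0 success, 1 usage error, 2 data error.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    message("usage: popgenpipe <simulate|paper-pipeline> [--config yaml] ",
            "[--seed int] [--out-dir dir] [--log-level info|quiet]")
    1L
  }
  if (!length(args)) return(usage())
  cmd <- args[1]; args <- args[-1]
  opts <- list(config = NULL, seed = NULL, out_dir = "popgenpipe_out",
               log_level = "info")
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    key <- gsub("-", "_", key)
    if (!key %in% names(opts) || i == length(args)) return(usage())
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  status <- tryCatch({
    cfg <- if (!is.null(opts$config)) read_pipeline_config(opts$config)
           else pipeline_config()
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    cfg$log_level <- opts$log_level
    if (cmd %in% c("paper-pipeline", "pipeline")) {
      run_pipeline(cfg, out_dir = opts$out_dir)
      0L
    } else if (cmd == "simulate") {
      set.seed(cfg$seed)
      sim <- simulate_two_pops(do.call(sim_config,
        c(cfg$simulate, list(seed = cfg$seed))))
      write_sim_outputs(sim, opts$out_dir)
      0L
    } else if (cmd == "filter") {
      gm <- read_vcf(cfg$inputs$vcf,
                     population_map = read_population_map(cfg$inputs$popmap))
      fl <- apply_filters(gm, do.call(filter_config, cfg$filter))
      dir.create(opts$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_vcf(fl$genotypes, file.path(opts$out_dir, "filtered.vcf"))
      write_tsv(fl$report, file.path(opts$out_dir, "filter_report.tsv"),
                params = cfg$filter, seed = cfg$seed)
      0L
    } else if (cmd == "rxy") {
      gm <- read_vcf(cfg$inputs$vcf,
                     population_map = read_population_map(cfg$inputs$popmap))
      ann <- read_annotation(cfg$inputs$annotation)
      pm <- infer_ancestral(gm, cfg$polarize$outgroup)
      out <- do.call(rbind, lapply(
        setdiff(unique(ann$category), "unannotated"), function(cat) {
          r <- rxy(pm, ann, cfg$rxy$pop_x, cfg$rxy$pop_y, cat,
                   n_blocks = cfg$rxy$n_blocks)
          data.frame(category = cat, freq_x = r$freq_x, freq_y = r$freq_y,
                     rxy = r$rxy, ci_low = r$ci_low, ci_high = r$ci_high)
        }))
      dir.create(opts$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_tsv(out, file.path(opts$out_dir, "rxy.tsv"),
                params = cfg$rxy, seed = cfg$seed)
      0L
    } else {
      message("unknown subcommand: ", cmd)
      1L
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  status
}
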