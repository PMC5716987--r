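## cli_pipeline: orchestrates synthetic-study generation -> preprocessing
## -> phylogenetic signals -> co-occurrence networks -> group statistics
## into one reproducible, seeded run with a config echo and structured log.

#' Default run configuration
#'
#' The `"paper"` profile carries the field-standard settings (rarefaction
#' depth 7,000; 1,000 null randomizations; 100 correlogram classes with
#' 999 permutations; top-500 OTUs; 9,999 SparCC permutations; thresholds
#' |rho| > 0.85, p < 0.01). The `"scaled"` profile keeps the thresholds
#' and depth but shrinks the permutation counts and network size so a full
#' run completes in minutes on one CPU.
#'
#' @param profile `"scaled"` (default) or `"paper"`.
#' @param seed master seed; every stage derives its own stream from it.
#' @param input_dir optional directory with `otu_table.tsv`, `tree.nwk`,
#'   `metadata.tsv`; when `NULL` a synthetic study is generated.
#' @param ... named overrides of any config field.
#' @return list of class `run_config`.
#' @export
default_run_config <- function(profile = c("scaled", "paper"), seed = 1L,
                               input_dir = NULL, ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    seed = as.integer(seed),
    input_dir = input_dir,
    n_tips = 500L,
    n_taxa_community = 75L,
    synth_depth = 10000L,
    rarefy_depth = 7000L,
    n_rand = if (profile == "paper") 1000L else 99L,
    correlog_classes = if (profile == "paper") 100L else 50L,
    correlog_perms = if (profile == "paper") 999L else 99L,
    top_k = if (profile == "paper") 500L else 100L,
    sparcc_perms = if (profile == "paper") 9999L else 99L,
    cscore_nulls = if (profile == "paper") 1000L else 199L,
    rho_thresh = 0.85,
    p_thresh = 0.01,
    skip_network = FALSE,
    skip_correlogram = FALSE,
    env_variable = "AP")
  override <- list(...)
  cfg[names(override)] <- override
  class(cfg) <- "run_config"
  cfg
}

.log_line <- function(log_path, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg)
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
  message(line)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full community-assembly pipeline
#'
#' Stages: (1) generate or load the study; (2) rarefy counts to even
#' depth; (3) Mantel correlogram of phylogenetic signal in environmental
#' optima; (4) per-sample alpha MPD/NRI with Tukey letters and the t-test
#' against +2; (5) within-group beta MPD/betaNRI and group means; (6) per
#' treatment: dominant-OTU selection, SparCC with permutation p-values,
#' thresholded network, topology metrics, C-score null test, GraphML and
#' edge-list export; (7) Pearson correlation panel and quadratic yield
#' fit. Every stage draws its randomness from a stream derived from the
#' master seed, so a rerun with the same config reproduces the outputs.
#'
#' @param config a [default_run_config()] list.
#' @param out_dir results directory (created; default `config$out_dir` or
#'   a temporary directory).
#' @return invisibly, a list with the main result tables and `out_dir`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  out_dir <- out_dir %||% config$out_dir %||% file.path(tempdir(), "commassembly_run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null",
                               digits = NA, pretty = TRUE)
  cfg_hash <- fnv1a_hash(as.character(cfg_json))
  writeLines(as.character(cfg_json), file.path(out_dir, "config.json"))
  .log_line(log_path, "config", sprintf("hash %s, profile %s, seed %d",
                                        cfg_hash, config$profile, config$seed))
  seed <- config$seed
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    .log_line(log_path, name, sprintf("done in %.1fs",
                                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  ## 1. inputs -------------------------------------------------------------
  study <- stage("inputs", {
    if (is.null(config$input_dir)) {
      st <- make_study(n_tips = config$n_tips,
                       design = default_study_design(config$n_taxa_community),
                       seed = derive_seed(seed, 10L),
                       depth = config$synth_depth)
      write_study(st, file.path(out_dir, "synthetic_study"))
      st
    } else {
      counts <- read_otu_table(file.path(config$input_dir, "otu_table.tsv"))
      list(counts = counts,
           tree = read_tree_newick(file.path(config$input_dir, "tree.nwk")),
           metadata = read_sample_metadata(file.path(config$input_dir, "metadata.tsv"),
                                           counts))
    }
  })
  counts <- study$counts
  tree <- study$tree
  metadata <- study$metadata

  ## 2. preprocess ---------------------------------------------------------
  rare <- stage("rarefy", rarefy(counts, depth = config$rarefy_depth,
                                 seed = derive_seed(seed, 20L)))
  f <- relative_abundance(rare)
  D <- stage("cophenetic", cophenetic_distances(tree))
  pool <- tree$tip.label

  ## 3. phylogenetic signal ------------------------------------------------
  correlogram <- NULL
  if (!isTRUE(config$skip_correlogram)) {
    correlogram <- stage("correlogram", {
      env <- stats::setNames(metadata[[config$env_variable]], metadata$sample_id)
      opt <- environmental_optimum(f, env)
      Dopt <- as.matrix(stats::dist(opt))
      cg <- mantel_correlogram(D[names(opt), names(opt)], Dopt,
                               n_classes = config$correlog_classes,
                               n_perm = config$correlog_perms,
                               seed = derive_seed(seed, 30L))
      .write_tsv(as.data.frame(cg), file.path(out_dir, "correlogram.tsv"))
      cg
    })
  }

  ## 4. alpha diversity ----------------------------------------------------
  alpha <- stage("alpha", {
    a <- alpha_diversity_table(f, D, pool, n_rand = config$n_rand,
                               seed = derive_seed(seed, 40L))
    a$group <- metadata$group[match(a$sample_id, metadata$sample_id)]
    .write_tsv(a, file.path(out_dir, "alpha.tsv"))
    a
  })
  letters_tab <- stage("letters", {
    lt <- tukey_letters(alpha$nri, alpha$group)
    .write_tsv(as.data.frame(lt), file.path(out_dir, "letters.tsv"))
    lt
  })
  nri_test <- stage("nri_ttest", ttest_vs_threshold(alpha$nri, 2))
  .log_line(log_path, "nri_ttest", nri_test$verdict)

  ## 5. beta diversity (within-group pairs) --------------------------------
  beta <- stage("beta", {
    groups <- split(metadata$sample_id, metadata$group)
    pairs <- do.call(rbind, lapply(groups, function(s) {
      if (length(s) < 2L) return(NULL)
      cmb <- utils::combn(s, 2L)
      data.frame(sample_1 = cmb[1L, ], sample_2 = cmb[2L, ],
                 stringsAsFactors = FALSE)
    }))
    b <- beta_diversity_table(f, D, pairs = pairs, pool_ids = pool,
                              n_rand = config$n_rand,
                              seed = derive_seed(seed, 50L))
    .write_tsv(b, file.path(out_dir, "beta.tsv"))
    b
  })
  beta_groups <- stage("beta_groups", {
    g1 <- group_mean_beta(beta, metadata, "beta_mpd_observed")
    g2 <- group_mean_beta(beta, metadata, "beta_nri")
    g <- merge(g1, g2, by = c("group", "n_samples", "n_pairs"),
               suffixes = c("_beta_mpd", "_beta_nri"))
    .write_tsv(g, file.path(out_dir, "beta_groups.tsv"))
    g
  })

  ## 6. networks per treatment ---------------------------------------------
  topology <- NULL
  if (!isTRUE(config$skip_network)) {
    topology <- stage("networks", {
      records <- list()
      cscores <- list()
      i <- 0L
      for (tr in unique(metadata$group)) {
        i <- i + 1L
        samp <- metadata$sample_id[metadata$group == tr]
        sub <- rare[samp, , drop = FALSE]
        sub <- sub[, colSums(sub) > 0, drop = FALSE]
        sub <- top_k_otus(sub, config$top_k)
        sp <- sparcc_pvalues(sub, n_perm = config$sparcc_perms,
                             seed = derive_seed(seed, 60L + i))
        net <- build_network(sp, rho_thresh = config$rho_thresh,
                             p_thresh = config$p_thresh)
        write_network_graphml(net, file.path(out_dir, sprintf("network_%s.graphml", tr)))
        write_edge_list(net, file.path(out_dir, sprintf("edges_%s.tsv", tr)))
        records[[tr]] <- topology_metrics(net, seed = derive_seed(seed, 80L + i))
        cscores[[tr]] <- data.frame(group = tr,
          as.data.frame(c_score_null_test(t(to_presence_absence(sub)),
                                          n_null = config$cscore_nulls,
                                          seed = derive_seed(seed, 90L + i))),
          stringsAsFactors = FALSE)
      }
      topo <- compare_networks(records)
      .write_tsv(topo, file.path(out_dir, "topology.tsv"))
      .write_tsv(do.call(rbind, cscores), file.path(out_dir, "cscore.tsv"))
      topo
    })
  }

  ## 7. statistics panel ---------------------------------------------------
  panel <- stage("panel", {
    covars <- intersect(c("pH", "SOC", "TN", "AK", "AP", "Ivt", "MC"),
                        names(metadata))
    d <- data.frame(metadata[match(alpha$sample_id, metadata$sample_id),
                             covars, drop = FALSE],
                    richness = alpha$richness,
                    alpha_mpd = alpha$observed,
                    alpha_nri = alpha$nri)
    pn <- pearson_panel(d)
    .write_tsv(as.data.frame(pn), file.path(out_dir, "panel.tsv"))
    pn
  })
  quad <- NULL
  if ("yield" %in% names(metadata)) {
    quad <- stage("quadratic_yield", {
      yield <- metadata$yield[match(alpha$sample_id, metadata$sample_id)]
      q <- quadratic_fit(alpha$nri, yield)
      .write_tsv(data.frame(a = q$coefficients["a"], b = q$coefficients["b"],
                            c = q$coefficients["c"], R = q$R, p = q$p,
                            vertex = q$vertex, linear_R = q$linear_R),
                 file.path(out_dir, "quad.tsv"))
      q
    })
  }

  .log_line(log_path, "done", sprintf("results in %s", out_dir))
  invisible(list(out_dir = out_dir, config = config, config_hash = cfg_hash,
                 alpha = alpha, beta = beta, beta_groups = beta_groups,
                 correlogram = correlogram, topology = topology,
                 letters = letters_tab, nri_test = nri_test,
                 panel = panel, quad = quad))
}
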