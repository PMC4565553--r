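# Staged orchestration: run the full analysis from one JSON config on the
# synthetic domain-family fixture (or user-supplied inputs), with per-stage
# seeds, timings, outputs under per-stage subdirectories and a checksum
# manifest.

#' Default demonstration configuration
#'
#' Runs every stage on the synthetic five-group domain-family fixture at
#' desk scale.
#'
#' @param out_dir output directory.
#' @param seed base seed.
#' @return config list accepted by [run_pipeline()].
#' @export
demo_config <- function(out_dir = tempfile("domevol_run_"), seed = 1) {
  list(
    out_dir = out_dir,
    seed = seed,
    stages = c("simdata", "asr", "calibrate_asr", "calibrate_fpr",
               "geneconv", "profiles", "network", "kinetics"),
    fixture = list(n_groups = 5, taxa_per_group = 6, n_sites = 60,
                   alpha = 0.8, ncat = 4),
    calibrate_asr = list(n_reps = 3, n_sites = 60),
    calibrate_fpr = list(n_reps = 2, n_taxa = 8, n_codons = 60,
                         n_branches = 2),
    geneconv = list(n_perm = 200),
    kinetics = list(Kd_true = 3e-8, noise_sd = 0.01, duration = 1200)
  )
}

.stage_log <- function(con, stage, t0) {
  msg <- sprintf("%s\t%.2fs", stage, as.numeric(Sys.time()) - t0)
  writeLines(msg, con)
  message("[domevol] ", msg)
}

#' Run the staged analysis pipeline
#'
#' Stages execute in dependency order; every random stage derives its seed
#' from the config seed; outputs are written under per-stage subdirectories
#' of `out_dir`, and a manifest of every file with md5 checksums is written
#' at the end.  The first failing stage aborts with a stage-named error
#' (partial outputs are retained).
#'
#' @param config config list (see [demo_config()]) or path to a JSON file.
#' @return invisibly, a list with per-stage results and the manifest.
#' @export
run_pipeline <- function(config = demo_config()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  out_dir <- config$out_dir %||% stop("config lacks out_dir")
  stages <- config$stages
  known <- c("simdata", "asr", "calibrate_asr", "calibrate_fpr", "geneconv",
             "profiles", "network", "kinetics")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  # pre-flight: any configured input paths must exist before execution
  for (p in unlist(config$inputs)) {
    if (!file.exists(p)) stop("pre-flight validation: missing input ", p)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1
  logfile <- file.path(out_dir, "run.log")
  logcon <- file(logfile, "w")
  on.exit(close(logcon), add = TRUE)
  results <- list()
  fixture <- NULL

  run_stage <- function(stage, fn) {
    t0 <- as.numeric(Sys.time())
    sd <- file.path(out_dir, stage)
    dir.create(sd, showWarnings = FALSE)
    res <- tryCatch(fn(sd), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    .stage_log(logcon, stage, t0)
    res
  }

  need_fixture <- function() {
    if (is.null(fixture)) {
      fx <- config$fixture %||% list()
      fixture <<- card_family_fixture(
        seed = seed,
        n_groups = fx$n_groups %||% 5, taxa_per_group = fx$taxa_per_group %||% 6,
        n_sites = fx$n_sites %||% 60, alpha = fx$alpha %||% 0.8,
        ncat = fx$ncat %||% 4)
    }
    fixture
  }

  for (stage in stages) {
    results[[stage]] <- switch(stage,
      simdata = run_stage("simdata", function(sd) {
        fx <- need_fixture()
        recs <- data.frame(id = rownames(fx$alignment),
                           seq = apply(fx$alignment, 1, paste, collapse = ""))
        write_fasta(recs, file.path(sd, "alignment.fasta"))
        ape::write.tree(fx$tree, file.path(sd, "tree.nwk"))
        utils::write.table(data.frame(taxon = names(fx$groups), group = fx$groups),
                           file.path(sd, "groups.tsv"), sep = "\t",
                           row.names = FALSE, quote = FALSE)
        invisible(fx)
      }),
      asr = run_stage("asr", function(sd) {
        fx <- need_fixture()
        rec <- marginal_reconstruct(fx$alignment, fx$tree, fx$model)
        ind <- parsimony_indels(fx$alignment, fx$tree)
        for (key in intersect(names(rec$nodes), rownames(ind$presence)))
          rec$nodes[[key]]$presence <- ind$presence[key, ]
        write_ancestral_fasta(rec, file.path(sd, "ancestors.fasta"))
        cs <- confidence_summary(rec)
        utils::write.table(cs$per_node, file.path(sd, "confidence.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        jsonlite::write_json(cs$pooled, file.path(sd, "confidence_pooled.json"),
                             auto_unbox = TRUE, digits = NA)
        list(reconstruction = rec, summary = cs)
      }),
      calibrate_asr = run_stage("calibrate_asr", function(sd) {
        fx <- need_fixture()
        cfg <- config$calibrate_asr %||% list()
        rep <- asr_error_experiment(fx$tree, fx$model,
                                    n_sites = cfg$n_sites %||% 60,
                                    n_reps = cfg$n_reps %||% 3,
                                    seed = seed * 100)
        utils::write.table(rep$per_node, file.path(sd, "asr_error.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        jsonlite::write_json(rep$calibration, file.path(sd, "calibration.json"),
                             auto_unbox = TRUE, digits = NA)
        rep
      }),
      calibrate_fpr = run_stage("calibrate_fpr", function(sd) {
        cfg <- config$calibrate_fpr %||% list()
        tr <- random_tree(cfg$n_taxa %||% 8, total_length = 2, seed = seed)
        ntip <- length(tr$tip.label)
        internal <- setdiff(unique(tr$edge[, 2]), seq_len(ntip))
        tested <- as.list(internal[seq_len(min(cfg$n_branches %||% 2,
                                               length(internal)))])
        rep <- branch_site_fpr_experiment(
          tr, codon_model(kappa = 2), regime = "neutral",
          n_reps = cfg$n_reps %||% 2, tested_branches = tested,
          n_codons = cfg$n_codons %||% 60, seed = seed * 1000)
        jsonlite::write_json(rep[c("fpr", "mean", "se", "alpha", "n_reps")],
                             file.path(sd, "fpr.json"), auto_unbox = TRUE,
                             digits = NA)
        rep
      }),
      geneconv = run_stage("geneconv", function(sd) {
        cfg <- config$geneconv %||% list()
        set.seed(seed * 7)
        n <- 5; L <- 120
        m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
        rownames(m) <- paste0("s", 1:n)
        res <- gene_conversion_scan(m, n_perm = cfg$n_perm %||% 200,
                                    seed = seed * 7 + 1)
        utils::write.table(res, file.path(sd, "geneconv.tsv"), sep = "\t",
                           row.names = FALSE, quote = FALSE)
        res
      }),
      profiles = run_stage("profiles", function(sd) {
        fx <- need_fixture()
        hmms <- lapply(split(rownames(fx$alignment), fx$groups), function(tx)
          build_hmm(fx$alignment[tx, , drop = FALSE]))
        tr <- hmm_tree(hmms)
        ape::write.tree(tr, file.path(sd, "hmm_tree.nwk"))
        utils::write.table(attr(tr, "distances"),
                           file.path(sd, "hmm_distances.tsv"), sep = "\t",
                           quote = FALSE)
        list(hmms = hmms, tree = tr)
      }),
      network = run_stage("network", function(sd) {
        fx <- need_fixture()
        seqs <- apply(fx$alignment, 1, paste, collapse = "")
        net <- similarity_network(seqs, groups = fx$groups)
        export_network(net, graphml_path = file.path(sd, "network.graphml"),
                       edgelist_path = file.path(sd, "edges.tsv"))
        net
      }),
      kinetics = run_stage("kinetics", function(sd) {
        cfg <- config$kinetics %||% list()
        spec <- kinetics_sim_spec(Kd_true = cfg$Kd_true %||% 3e-8,
                                  noise_sd = cfg$noise_sd %||% 0.01,
                                  duration = cfg$duration %||% 1200,
                                  seed = seed * 11)
        traces <- simulate_kinetics(spec)
        write_traces(traces, file.path(sd, "traces.csv"))
        est <- estimate_binding(traces, scheme = "per_replicate")
        est_avg <- estimate_binding(traces, scheme = "averaged")
        tab <- data.frame(
          scheme = c("per_replicate", "averaged"),
          Kd = c(est$Kd$K_mean, est_avg$Kd$K_mean),
          pKd = c(est$Kd$pK_mean, est_avg$Kd$pK_mean),
          Km = c(est$Km$K_mean, est_avg$Km$K_mean),
          pKm = c(est$Km$pK_mean, est_avg$Km$pK_mean))
        utils::write.table(tab, file.path(sd, "binding.tsv"), sep = "\t",
                           row.names = FALSE, quote = FALSE)
        list(per_replicate = est, averaged = est_avg, table = tab)
      }))
  }
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.tsv"))
  manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)))
  manifest <- manifest[manifest$file != "run.log", ]
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(list(results = results, manifest = manifest, out_dir = out_dir))
}
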