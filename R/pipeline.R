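# End-to-end orchestration: fixture generation, staged execution on a
# directory of input tables, summary report and run manifest.

.log_line <- function(log_path, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  paste0(...))
  if (!is.null(log_path)) cat(line, "\n", file = log_path, append = TRUE)
  message(line)
}

#' Write a complete synthetic fixture directory
#'
#' Generates every input table the pipeline consumes — paired count and TPM
#' matrices with designs, gene annotation, ribosome-fraction protein
#' intensities, corem membership with an expression compendium and condition
#' categories, and a bait-prey edge list — plus the planted truth tables and
#' a configuration file. `scale = "study"` mirrors the dimensions of the
#' growth-phase study (2663 genes with the observed class sizes, 58 annotated
#' ribosomal-protein genes of which 54 sit in 72 corems, a 7-module
#' interaction network with 14 baits); `"tiny"` is a down-scaled smoke
#' fixture.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param scale `"tiny"` or `"study"`.
#' @return The directory path, invisibly; files are tab-separated tables plus
#'   `config.yaml`.
#' @export
make_fixture <- function(dir, seed = 1L, scale = c("tiny", "study")) {
  scale <- match.arg(scale)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (scale == "study") {
    props <- c(.default_class_counts, "NOT_ASSESSED" = 1256)
    n_genes <- 2663
    n_rp_genes <- 58
    stoich <- stoich_sim_params(n_rp = 50,
                                deviant_offsets = default_deviant_rps(),
                                seed = stage_seed(seed, "stoich"))
    corem <- simulate_corems(n_genes = 54, n_corems = 72,
                             class_sizes = c(38, 7, 6, 3), noise_rate = 0.05,
                             n_unassigned = 4, seed = stage_seed(seed, "corem"))
    ppi <- simulate_ppi(n_nodes = 128, n_modules = 7, p_in = 0.7,
                        p_out = 0.04, n_baits = 2, rp_fraction = 0.12,
                        seed = stage_seed(seed, "ppi"))
  } else {
    props <- c("TC+" = 40, "TC-" = 40, "COMP-" = 12, "COMP+" = 10,
               "TL+" = 6, "TL-" = 6, "NR" = 36)
    n_genes <- 200
    n_rp_genes <- 12
    stoich <- stoich_sim_params(n_rp = 24,
                                deviant_offsets = default_deviant_rps()[c(1, 3)],
                                seed = stage_seed(seed, "stoich"))
    corem <- simulate_corems(n_genes = 24, n_corems = 24,
                             class_sizes = c(10, 6, 5, 3), noise_rate = 0.05,
                             n_unassigned = 2, n_conditions = 45,
                             n_categories = 3, seed = stage_seed(seed, "corem"))
    ppi <- simulate_ppi(n_nodes = 30, n_modules = 3, p_in = 0.8, p_out = 0.05,
                        n_baits = 2, rp_fraction = 0.15,
                        seed = stage_seed(seed, "ppi"))
  }
  params <- sim_params(seed = stage_seed(seed, "counts"))
  truth <- simulate_truth(n_genes, props, params)
  truth$is_rp <- seq_len(n_genes) %in%
    utils::head(which(truth$true_class %in% c("TC+", "TC-")), n_rp_genes)
  sim <- simulate_paired_counts(truth, params = params)
  prot <- simulate_rp_proteomics(stoich)

  p <- function(f) file.path(dir, f)
  write_table(sim$mrna_counts, p("mrna_counts.tsv"))
  write_table(sim$ribo_counts, p("ribo_counts.tsv"))
  write_table(sim$mrna_tpm, p("mrna_tpm.tsv"))
  write_table(sim$ribo_tpm, p("ribo_tpm.tsv"))
  write_table(rbind(sim$design_rna, sim$design_ribo), p("design.tsv"))
  ann <- data.frame(gene_id = truth$gene_id, is_rp = truth$is_rp,
                    rp_name = ifelse(truth$is_rp,
                                     sprintf("RPG%02d", cumsum(truth$is_rp)),
                                     NA_character_),
                    stringsAsFactors = FALSE)
  write_table(ann, p("annotation.tsv"))
  write_table(prot$intensity, p("protein_intensity.tsv"), id_name = "protein_id")
  write_table(prot$design, p("protein_design.tsv"))
  write_table(corem$membership, p("corem_membership.tsv"))
  write_table(corem$compendium, p("compendium.tsv"))
  write_table(corem$condition_categories, p("condition_categories.tsv"))
  write_table(ppi$edges, p("ppi_edges.tsv"))
  write_table(ppi$roles, p("ppi_roles.tsv"))
  # planted ground truth, for tests and recovery scoring only
  write_table(truth, p("truth_genes.tsv"))
  write_table(prot$truth, p("truth_rp.tsv"))
  write_table(corem$truth, p("truth_corem_classes.tsv"))
  write_table(ppi$truth, p("truth_ppi_modules.tsv"))
  write_config(pipeline_config(random_seed = seed), p("config.yaml"))
  invisible(dir)
}

.stage_inputs <- list(
  differential = c("mrna_counts.tsv", "ribo_counts.tsv", "design.tsv"),
  interplay = c("mrna_tpm.tsv", "ribo_tpm.tsv", "design.tsv"),
  stoichiometry = c("protein_intensity.tsv", "protein_design.tsv"),
  corems = c("corem_membership.tsv", "compendium.tsv", "condition_categories.tsv"),
  ppi = c("ppi_edges.tsv")
)

#' Run the full pipeline on a fixture directory
#'
#' Executes differential testing (TP-last vs TP1 for both assays),
#' regulatory-class assignment, TE computation and regression with binned
#' residual tests and a permutation abundance test on the translationally
#' upregulated set, ribosomal-protein stoichiometry flagging, corem
#' clustering with class similarity matrices, and interaction-network module
#' detection. Stages whose input tables are missing are skipped and logged.
#' Outputs, a plain-text summary and a JSON manifest (config snapshot, input
#' checksums, per-stage status) land in `output_dir`.
#'
#' @param input_dir Directory with the input tables (see [make_fixture()] for
#'   the file names).
#' @param output_dir Output directory (created if needed).
#' @param cfg A [pipeline_config()]; defaults to `config.yaml` in
#'   `input_dir` when present.
#' @param n_boot Bootstrap resamples for the corem stage (defaults to the
#'   config value).
#' @return The manifest list, invisibly.
#' @export
run_all <- function(input_dir, output_dir, cfg = NULL, n_boot = NULL) {
  if (is.null(cfg)) {
    cfg_path <- file.path(input_dir, "config.yaml")
    cfg <- if (file.exists(cfg_path)) read_config(cfg_path) else pipeline_config()
  }
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(n_boot)) n_boot <- cfg$n_bootstrap
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(output_dir, "run.log")
  if (file.exists(log_path)) file.remove(log_path)
  summary_lines <- character(0)
  add <- function(...) summary_lines <<- c(summary_lines, sprintf(...))
  status <- list()
  have <- function(stage) {
    files <- file.path(input_dir, .stage_inputs[[stage]])
    ok <- all(file.exists(files))
    if (!ok) {
      .log_line(log_path, "skipping ", stage, ": missing ",
                paste(basename(files[!file.exists(files)]), collapse = ", "))
      status[[stage]] <<- "skipped"
    }
    ok
  }
  outputs <- character(0)
  save <- function(obj, name, ...) {
    path <- file.path(output_dir, name)
    write_table(obj, path, ...)
    outputs <<- c(outputs, path)
  }

  classes <- NULL
  mrna_res <- NULL
  if (have("differential")) {
    design <- read_table(file.path(input_dir, "design.tsv"), "design")
    tps <- unique(design$time_point)
    last_tp <- tps[length(tps)]
    mrna <- read_table(file.path(input_dir, "mrna_counts.tsv"), "counts",
                       design = design)
    ribo <- read_table(file.path(input_dir, "ribo_counts.tsv"), "counts",
                       design = design)
    .log_line(log_path, "differential: ", nrow(mrna), " genes, contrast ",
              last_tp, " vs ", tps[1], ", |lfc| > ", cfg$fc_threshold,
              ", alpha ", cfg$alpha)
    mrna_res <- differential_expression(mrna, design[design$assay == "rna", ],
                                        last_tp, tps[1], cfg, assay = "rna")
    ribo_res <- differential_expression(ribo, design[design$assay == "ribo", ],
                                        last_tp, tps[1], cfg, assay = "ribo")
    save(mrna_res, "differential_mrna.tsv")
    save(ribo_res, "differential_ribo.tsv")
    classes <- classify_regulation(mrna_res, ribo_res, cfg)
    save(as.data.frame(classes), "regulatory_classes.tsv")
    cnt <- attr(classes, "counts")
    .log_line(log_path, "classification: ",
              paste(names(cnt), cnt, sep = "=", collapse = " "))
    add("Regulatory classes: %s",
        paste(names(cnt), cnt, sep = "=", collapse = " "))
    status$differential <- "ok"
  }

  if (have("interplay")) {
    design <- read_table(file.path(input_dir, "design.tsv"), "design")
    tps <- unique(design$time_point)
    rna_tpm <- read_table(file.path(input_dir, "mrna_tpm.tsv"), "abundance")
    ribo_tpm <- read_table(file.path(input_dir, "ribo_tpm.tsv"), "abundance")
    te <- compute_te(rna_tpm, ribo_tpm, design[design$assay == "rna", ],
                     design[design$assay == "ribo", ], tps[1], cfg)
    fit <- regress_te_on_abundance(te, level = cfg$ci_level)
    .log_line(log_path, "TE regression (", tps[1], "): slope ",
              round(fit$slope, 3), ", R ", round(fit$r, 3), ", n ", fit$n)
    add("TE regression at %s: slope a = %.3f, R = %.3f (n = %d, p = %.3g)",
        tps[1], fit$slope, fit$r, fit$n, fit$pvalue)
    save(data.frame(slope = fit$slope, intercept = fit$intercept, r = fit$r,
                    r_squared = fit$r_squared, pvalue = fit$pvalue, n = fit$n),
         "te_regression.tsv")
    save(te, "te_values.tsv")
    if (!is.null(mrna_res)) {
      dev <- te_deviation_by_group(fit, mrna_res, cfg)
      save(dev, "te_deviation_by_group.tsv")
    }
    if (!is.null(classes)) {
      tl_up <- classes$gene_id[classes$class == "TL+"]
      if (length(tl_up) >= 1) {
        ab <- stats::setNames(te$tpm_rna, te$gene_id)
        pt <- permutation_abundance_test(tl_up, ab,
                                         n_perm = cfg$n_permutations,
                                         seed = stage_seed(cfg$random_seed,
                                                           "permutation"))
        add("TL+ abundance permutation test: n = %d, p = %.4g",
            length(tl_up), pt$p)
        save(data.frame(set = "TL+", n = length(tl_up), p = pt$p,
                        observed_mean = pt$observed, null_mean = pt$null_mean),
             "tl_up_permutation.tsv")
      }
    }
    status$interplay <- "ok"
  }

  if (have("stoichiometry")) {
    prot <- read_table(file.path(input_dir, "protein_intensity.tsv"), "protein")
    pdes <- read_table(file.path(input_dir, "protein_design.tsv"), "design")
    .log_line(log_path, "stoichiometry: ", nrow(prot), " proteins, CI ",
              cfg$ci_level, ", min events ", cfg$min_deviation_events)
    st <- stoichiometry_analysis(prot, pdes, cfg)
    save(as.data.frame(st), "stoichiometry.tsv")
    fl <- unique(st$rp_name[st$flagged])
    add("Stoichiometry: %d proteins, flagged: %s", nrow(prot),
        if (length(fl)) paste(fl, collapse = ", ") else "none")
    status$stoichiometry <- "ok"
  }

  if (have("corems")) {
    mem <- read_table(file.path(input_dir, "corem_membership.tsv"), "membership")
    comp <- read_table(file.path(input_dir, "compendium.tsv"), "compendium")
    cats <- utils::read.delim(file.path(input_dir, "condition_categories.tsv"),
                              stringsAsFactors = FALSE)
    .log_line(log_path, "corems: ", nrow(mem), " genes x ", ncol(mem),
              " corems, ", n_boot, " bootstrap resamples")
    assign_ <- bootstrap_cluster_support(mem, n_boot = n_boot,
                                         seed = stage_seed(cfg$random_seed,
                                                           "bootstrap"))
    save(as.data.frame(assign_), "corem_classes.tsv")
    n_cls <- length(setdiff(unique(assign_$class_label), "unassigned"))
    add("Corem classes: %d (supports %s); %d unassigned, %d excluded",
        n_cls,
        paste(sprintf("%.2f", unique(stats::na.omit(assign_$cluster_support))),
              collapse = ", "),
        sum(assign_$class_label == "unassigned"),
        length(attr(assign_, "excluded")))
    sim_mats <- class_similarity_matrix(assign_, mem, comp, cats, cfg)
    for (nm in names(sim_mats)) {
      save(sim_mats[[nm]], paste0("class_similarity_", nm, ".tsv"),
           id_name = "class")
    }
    status$corems <- "ok"
  }

  if (have("ppi")) {
    edges <- read_table(file.path(input_dir, "ppi_edges.tsv"), "edges")
    roles_path <- file.path(input_dir, "ppi_roles.tsv")
    roles <- if (file.exists(roles_path)) {
      utils::read.delim(roles_path, stringsAsFactors = FALSE)
    } else NULL
    net <- build_network(edges, roles)
    .log_line(log_path, "ppi: ", net$counts["nodes"], " nodes, ",
              net$counts["edges"], " edges (",
              net$counts["duplicates_removed"], " duplicates removed)")
    mods <- girvan_newman_modules(net)
    save(mods, "ppi_modules.tsv")
    add("PPI network: %d nodes, %d edges, %d modules (Q = %.3f)",
        net$counts["nodes"], net$counts["edges"],
        length(unique(mods$module)), attr(mods, "modularity"))
    if (!is.null(roles) && any(roles$role == "RP")) {
      sub <- extract_bait_prey_subnetwork(net)
      save(sub$edges, "tf_rp_edges.tsv")
      add("Transcription-machinery -> RP interactions: %d", sub$n)
    }
    status$ppi <- "ok"
  }

  writeLines(c("Pipeline summary", "================", summary_lines),
             file.path(output_dir, "summary.txt"))
  inputs <- list.files(input_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    config = unclass(cfg),
    seed = cfg$random_seed,
    input_checksums = as.list(stats::setNames(unname(tools::md5sum(inputs)),
                                              basename(inputs))),
    stages = status,
    outputs = basename(outputs)
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
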