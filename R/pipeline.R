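# End-to-end orchestration: simulate (or load) -> COGs -> tree -> events ->
# pairwise omega comparison -> branch test -> site test -> theta-II, with
# deterministic per-stage seeding and report tables written as TSV.

#' Run the full comparative-evolution pipeline
#'
#' Stages run in order; each writes one report table into `out_dir`:
#' `events.tsv` (per-clade duplication/loss counts), `branch_test.tsv`
#' (one-ratio vs two-ratio fits with the LRT), `site_model.tsv` and
#' `selected_sites.tsv` (M3 parameters and positively selected sites),
#' `omega_comparison.tsv` (paired clade comparison per orthologous subfamily
#' pair), `theta2.tsv` (type-II divergence per cluster pair), plus
#' `subfamilies.tsv`, `gene_tree.nwk`, a JSON `manifest.json` (config hash,
#' seeds, versions) and `pipeline.log`. Re-running with the same config
#' reproduces every numeric output.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   * `simulate`: arguments for [sim_config()] (used when no `aln` given),
#'   * `aln`, `clade_map`, `tree`, `hits`: input file paths,
#'   * `out_dir` (required), `seed`, `alpha`, `bootstrap_reps`, `n_pairs`,
#'     `neb_threshold`, `lrt_df`, `min_support`,
#'   * `stages`: character vector selecting a subset of
#'     `c("cogs", "tree", "events", "omega", "branch_test", "site_test",
#'     "theta2")`.
#' @return Invisibly, a named list with every stage's tibble plus the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) stop("config$out_dir is required", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  alpha <- config$alpha %||% 0.05
  n_pairs <- config$n_pairs %||% 20
  boot <- config$bootstrap_reps %||% 200
  neb_thr <- config$neb_threshold %||% 0.95
  lrt_df <- config$lrt_df %||% 2
  min_support <- config$min_support %||% 50
  all_stages <- c(
    "cogs", "tree", "events", "omega", "branch_test",
    "site_test", "theta2"
  )
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }

  log_path <- file.path(config$out_dir, "pipeline.log")
  log_line <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), ..., "\n",
      file = log_path, append = TRUE
    )
  }
  cat("", file = log_path)
  run_stage <- function(name, expr) {
    log_line("stage", name, "start")
    out <- tryCatch(expr, error = function(e) {
      log_line("stage", name, "FAILED:", conditionMessage(e))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    log_line("stage", name, "done")
    out
  }
  results <- list()

  # ---- inputs --------------------------------------------------------------
  if (!is.null(config$aln)) {
    if (!file.exists(config$aln)) {
      stop("stage 'input' failed: alignment file not found: ", config$aln,
        call. = FALSE
      )
    }
    aln <- read_codon_fasta(config$aln)
    clade_map <- read_clade_map(config$clade_map)
    tree_in <- if (!is.null(config$tree)) ape::read.tree(config$tree) else NULL
    truth <- NULL
  } else {
    sim_args <- config$simulate %||% list()
    sim_args$seed <- sim_args$seed %||% seed
    cfg <- do.call(sim_config, sim_args)
    fam <- run_stage("simulate", simulate_family(cfg))
    write_sim_family(fam, file.path(config$out_dir, "simulated_family"))
    aln <- fam$aln
    clade_map <- fam$clade_map
    tree_in <- NULL
    truth <- fam$truth
    results$truth <- truth
  }
  hits <- if (!is.null(config$hits)) read_hits(config$hits) else NULL
  prot <- translate_alignment(aln)
  # expected species roster: an explicit TSV (species, clade), the simulated
  # configuration, or (fallback) the species observed in the clade map
  species_lists <- if (!is.null(config$roster)) {
    r <- readr::read_tsv(config$roster, show_col_types = FALSE)
    split(r$species, r$clade)
  } else if (is.null(config$aln)) {
    list(
      grass = paste0("g", seq_len(cfg$n_grass_species)),
      eudicot = paste0("e", seq_len(cfg$n_eudicot_species))
    )
  } else {
    split(
      unique(clade_map[c("species", "clade")])$species,
      unique(clade_map[c("species", "clade")])$clade
    )
  }

  # ---- stages --------------------------------------------------------------
  if ("cogs" %in% stages && !is.null(hits)) {
    results$cogs <- run_stage("cogs", cogs_from_hits(hits, clade_map))
    write_report(results$cogs, file.path(config$out_dir, "cogs.tsv"))
  }

  need_tree <- any(c("tree", "events", "omega", "theta2") %in% stages)
  if (need_tree) {
    tree <- run_stage("tree", {
      if (!is.null(tree_in)) {
        tree_in
      } else {
        bootstrap_support(prot,
          n_reps = boot,
          seed = branch_seed(seed, "bootstrap")
        )
      }
    })
    ape::write.tree(tree, file.path(config$out_dir, "gene_tree.nwk"))
    subfam <- run_stage(
      "tree",
      partition_subfamilies(tree, clade_map, min_support = min_support)
    )
    results$subfamilies <- subfam
    write_report(subfam, file.path(config$out_dir, "subfamilies.tsv"))
  }

  if ("events" %in% stages) {
    results$events <- run_stage("events", dplyr::bind_rows(
      classify_duplications(subfam, clade_map, species_lists),
      classify_losses(subfam, clade_map, species_lists)
    ))
    results$event_counts <- count_events(results$events)
    write_report(results$events, file.path(config$out_dir, "events.tsv"))
    write_report(
      results$event_counts,
      file.path(config$out_dir, "event_counts.tsv")
    )
  }

  if ("omega" %in% stages) {
    results$omega_comparison <- run_stage(
      "omega",
      compare_subfamily_omegas(aln, subfam,
        n_pairs = n_pairs,
        alpha = alpha, seed = branch_seed(seed, "omega")
      )
    )
    write_report(
      results$omega_comparison,
      file.path(config$out_dir, "omega_comparison.tsv")
    )
  }

  if ("branch_test" %in% stages) {
    results$branch_test <- run_stage("branch_test", {
      m0 <- fit_codon_model(aln, NULL, model = "M0")
      b2 <- fit_codon_model(aln, m0$tree,
        model = "BRANCH2",
        clade_map = clade_map, init = m0
      )
      test <- lrt(m0, b2, df = lrt_df)
      tibble::tibble(
        neg_lnL_null = -m0$lnL, omega_null = unname(m0$omega),
        neg_lnL_alt = -b2$lnL,
        omega_grass = unname(b2$omega["grass"]),
        omega_eudicot = unname(b2$omega["eudicot"]),
        statistic = test$statistic, df = test$df, p_value = test$p_value
      )
    })
    write_report(
      results$branch_test,
      file.path(config$out_dir, "branch_test.tsv")
    )
  }

  if ("site_test" %in% stages) {
    # clade-specific scans: the M3 site model is fitted to each clade's
    # genes separately, so selected sites carry a clade tag
    results$site_test <- run_stage("site_test", {
      out <- list()
      for (cl in c("grass", "eudicot")) {
        ids <- clade_map$gene_id[clade_map$clade == cl]
        sub <- aln |> dplyr::filter(.data$gene_id %in% ids)
        if (nrow(sub) < 3) next
        m3 <- fit_codon_model(sub, NULL, model = "M3K3")
        out[[cl]] <- list(
          fit = m3,
          selection = neb_sites(m3, sub, threshold = neb_thr)
        )
      }
      out
    })
    model_rows <- dplyr::bind_rows(lapply(
      names(results$site_test),
      function(cl) {
        m3 <- results$site_test[[cl]]$fit
        tibble::tibble(
          clade = cl, model = "M3K3", neg_lnL = -m3$lnL, kappa = m3$kappa,
          p1 = m3$props[1], p2 = m3$props[2], p3 = m3$props[3],
          omega1 = m3$omega[1], omega2 = m3$omega[2], omega3 = m3$omega[3],
          converged = m3$converged
        )
      }
    ))
    site_rows <- dplyr::bind_rows(lapply(
      names(results$site_test),
      function(cl) {
        results$site_test[[cl]]$selection$sites |>
          dplyr::filter(.data$selected) |>
          dplyr::mutate(clade = cl, .before = 1)
      }
    ))
    if (nrow(site_rows) == 0) {
      site_rows <- tibble::tibble(
        clade = character(0), site = integer(0),
        posterior_positive = numeric(0)
      )
    }
    write_report(model_rows, file.path(config$out_dir, "site_model.tsv"))
    write_report(site_rows, file.path(config$out_dir, "selected_sites.tsv"))
  }

  if ("theta2" %in% stages) {
    results$theta2 <- run_stage("theta2", theta2_table(prot, subfam))
    write_report(results$theta2, file.path(config$out_dir, "theta2.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cladeshift")),
    r_version = as.character(getRversion()),
    seed = seed,
    config_hash = rlang::hash(config),
    stages = stages
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  results$manifest <- manifest
  invisible(results)
}

# TSV writer with the report number format: 6 significant digits, p-values
# in scientific notation with the "<1.00e-12" floor.
write_report <- function(tab, path) {
  out <- tab
  for (nm in names(out)) {
    if (!is.numeric(out[[nm]])) next
    out[[nm]] <- if (grepl("^p_value", nm)) {
      format_p(out[[nm]])
    } else {
      vapply(out[[nm]], function(v) {
        if (is.na(v)) NA_character_ else format(signif(v, 6))
      }, character(1))
    }
  }
  readr::write_tsv(out, path)
  invisible(path)
}
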