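# End-to-end orchestration: preprocess -> network -> modules -> module-trait
# association -> hub ranking, writing every intermediate table plus a JSON
# manifest; and the synthetic-cohort writer.
#
# Machine outputs carry no timestamps, so identical inputs + config produce
# byte-identical files.

.write_tsv <- function(df, path) {
  write.table(format(as.data.frame(df), digits = 17, trim = TRUE,
                     scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  path
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
          class = "coex_stage_error")
  })
}

#' Run the full co-expression pipeline
#'
#' Executes preprocessing, network construction, module detection,
#' module-trait association and hub ranking, writing each result as TSV under
#' `out_dir` together with the resolved configuration and a JSON manifest.
#' On a stage failure the run aborts naming the stage, and any outputs
#' already written are renamed with a `.partial` suffix.
#'
#' @param expression Samples x features matrix, or a path readable by
#'   [read_expression_matrix()].
#' @param traits Trait tibble with `sample_id`, or a path readable by
#'   [read_trait_table()].
#' @param config A `coex_config` (default [coex_config()]).
#' @param out_dir Output directory (created if needed).
#' @param hub_trait Trait used for hub ranking; defaults to the first trait
#'   column. The hub module is the one with maximal `|r|` for that trait.
#' @return A manifest list (invisibly written as `manifest.json`): config
#'   snapshot, input digests, selected power, hub module/trait and per-stage
#'   output paths.
#' @export
run_pipeline <- function(expression, traits, config = coex_config(),
                         out_dir, hub_trait = NULL) {
  stopifnot(inherits(config, "coex_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  on_fail_cleanup <- function() {
    for (f in written) {
      if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
    }
  }
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    .write_tsv(df, path)
    written <<- c(written, path)
    path
  }
  digests <- list()
  result <- tryCatch({
    set.seed(config$seed)
    if (is.character(expression)) {
      digests$expression <- unname(tools::md5sum(expression))
      expression <- read_expression_matrix(expression)
    }
    if (is.character(traits)) {
      digests$traits <- unname(tools::md5sum(traits))
      traits <- read_trait_table(traits)
    }

    m <- .stage("preprocess", {
      x <- expression
      if (config$normalization == "quantile") x <- quantile_normalize(x)
      if (!is.null(config$filter_top_n) && config$filter_top_n < ncol(x)) {
        x <- filter_features(x, top_n = config$filter_top_n)$matrix
      }
      x
    })

    net <- .stage("network", {
      scan <- scan_soft_threshold(m, powers = config$powers,
                                  signed = config$signed)
      power <- pick_power(scan, r2_cut = config$r2_cut)
      cc <- correlation_matrix(m)
      a <- adjacency(cc, power = as.numeric(power), signed = config$signed)
      list(scan = scan, power = power, adjacency = a,
           tom = topological_overlap(a))
    })
    emit(tidy(net$scan), "soft_threshold_scan.tsv")

    mod <- .stage("modules", {
      dend <- cluster_features(net$tom)
      asg <- cut_tree(dend, height = config$cut_height,
                      min_size = config$min_module_size)
      if (any(asg$module != GREY_LABEL)) {
        merged <- merge_similar_modules(m, asg,
                                        max_dissimilarity = config$merge_dissimilarity)
      } else {
        abort("no module survived the cut; lower min_module_size or raise cut_height")
      }
      merged
    })
    emit(mod$assignment, "module_assignment.tsv")
    emit(module_sizes(mod$assignment), "module_sizes.tsv")
    emit(as_tibble(mod$eigengenes$eigengenes, rownames = "sample_id"),
         "eigengenes.tsv")

    mt <- .stage("traits", {
      correlate_with_traits(mod$eigengenes, traits,
                            method = config$trait_method,
                            p_adjust = config$p_adjust)
    })
    emit(tidy(mt), "module_trait.tsv")

    hub <- .stage("ranking", {
      trait_name <- hub_trait %||% setdiff(names(traits), "sample_id")[1]
      cells <- dplyr::filter(tidy(mt), .data$trait == trait_name)
      if (!nrow(cells)) abort(sprintf("no module-trait cell for trait '%s'", trait_name))
      hub_module <- cells$module[which.max(abs(cells$r))]
      members <- mod$assignment$feature_id[mod$assignment$module == hub_module]
      gs <- suppressWarnings(
        gene_significance(m[, members, drop = FALSE], traits, trait_name))
      centr <- if (config$centrality == "kIM") {
        intramodular_connectivity(net$tom[members, members, drop = FALSE],
                                  mod$assignment[mod$assignment$module == hub_module, ],
                                  hub_module)
      } else {
        kme <- module_membership(m[, members, drop = FALSE], mod$eigengenes)
        setNames(kme[, hub_module], members)
      }
      list(trait = trait_name, module = hub_module,
           ranking = rank_hub_genes(gs, centr, members))
    })
    emit(hub$ranking, "hub_ranking.tsv")

    cfg_path <- file.path(out_dir, "config.yaml")
    write_run_config(config, cfg_path)
    manifest <- list(
      tool = "coexrank",
      version = as.character(utils::packageVersion("coexrank")),
      seed = config$seed,
      config = unclass(config),
      input_digests = digests,
      selected_power = as.numeric(net$power),
      power_reached_cut = attr(net$power, "reached_cut"),
      hub_trait = hub$trait,
      hub_module = hub$module,
      outputs = written
    )
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    manifest
  }, error = function(e) {
    on_fail_cleanup()
    stop(e)
  })
  invisible(result)
}

#' Simulate and write a synthetic cohort
#'
#' Generates the default study-scale cohort (expression with planted modules,
#' linked + null traits, a peptide matrix with linear and parabolic responses)
#' and writes `expression.tsv`, `traits.tsv`, `peptides.tsv` and `truth.json`
#' under `out_dir`.
#'
#' @param config A `coex_config`; its `seed` drives all draws.
#' @param out_dir Output directory.
#' @param n_samples,module_sizes,loading,noise_sd,n_noise_features Passed to
#'   [generate_modular_expression()].
#' @param links Trait links passed to [generate_traits()].
#' @return Named list of the four file paths, invisibly.
#' @export
simulate_cohort <- function(config = coex_config(), out_dir,
                            n_samples = 40, module_sizes = rep(50, 5),
                            loading = 0.8, noise_sd = 0.6,
                            n_noise_features = 750,
                            links = list(MVD = list(module = "M1", rho = 0.7))) {
  stopifnot(inherits(config, "coex_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  sim <- generate_modular_expression(n_samples = n_samples,
                                     module_sizes = module_sizes,
                                     loading = loading, noise_sd = noise_sd,
                                     n_noise_features = n_noise_features,
                                     seed = seed)
  traits <- generate_traits(sim$truth, links = links, seed = seed + 1)
  target <- symmetric_target(n_samples, seed = seed + 2)
  pep <- generate_peptides(target, seed = seed + 3)
  paths <- list(
    expression = file.path(out_dir, "expression.tsv"),
    traits = file.path(out_dir, "traits.tsv"),
    peptides = file.path(out_dir, "peptides.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_expression_matrix(sim$expression, paths$expression)
  write_trait_table(traits, paths$traits)
  write_expression_matrix(pep$peptides, paths$peptides)
  jsonlite::write_json(list(
    seed = seed,
    rng = "Mersenne-Twister/Inversion",
    membership = sim$truth$membership,
    factors = as.data.frame(sim$truth$factors) |>
      (\(d) cbind(sample_id = rownames(sim$truth$factors), d))(),
    peptide_truth = pep$truth,
    peptide_target = target
  ), paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
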