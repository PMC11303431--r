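# Run configuration: one flat list of tunables shared by the pipeline stages,
# validated on construction and on load from YAML.

.config_defaults <- function() {
  list(
    # preprocess
    normalization     = "quantile",     # quantile | none
    filter_top_n      = 10000L,         # NULL disables variance filtering
    probe_collapse    = "none",         # none | max-variance
    # network
    powers            = c(1:10, 12, 14, 16, 18, 20),
    r2_cut            = 0.8,
    signed            = FALSE,
    # module detection
    cut_height        = 0.95,
    min_module_size   = 30L,
    merge_dissimilarity = 0.2,
    # trait association
    trait_method      = "pearson",      # pearson | spearman | auto
    p_adjust          = "none",         # none | BH
    # candidate ranking
    centrality        = "kIM",          # kIM | kME
    top_k             = 100L,
    # MIC
    mic_alpha         = 0.6,
    mic_c             = 15,
    # reproducibility
    seed              = 1L
  )
}

.validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(paste0("invalid config: ", msg))
  chk(cfg$normalization %in% c("quantile", "none"), "normalization must be 'quantile' or 'none'")
  chk(is.null(cfg$filter_top_n) ||
        (is.numeric(cfg$filter_top_n) && cfg$filter_top_n >= 1),
      "filter_top_n must be NULL or a positive count")
  chk(cfg$probe_collapse %in% c("none", "max-variance"), "probe_collapse")
  chk(is.numeric(cfg$powers) && length(cfg$powers) > 0 && all(cfg$powers >= 1),
      "powers must be numeric, all >= 1")
  chk(is.numeric(cfg$r2_cut) && cfg$r2_cut >= 0 && cfg$r2_cut <= 1, "r2_cut in [0,1]")
  chk(is.logical(cfg$signed), "signed must be logical")
  chk(is.numeric(cfg$cut_height) && cfg$cut_height > 0 && cfg$cut_height < 1,
      "cut_height in (0,1)")
  chk(is.numeric(cfg$min_module_size) && cfg$min_module_size >= 2, "min_module_size >= 2")
  chk(is.numeric(cfg$merge_dissimilarity) && cfg$merge_dissimilarity >= 0 &&
        cfg$merge_dissimilarity <= 1, "merge_dissimilarity in [0,1]")
  chk(cfg$trait_method %in% c("pearson", "spearman", "auto"), "trait_method")
  chk(cfg$p_adjust %in% c("none", "BH"), "p_adjust must be 'none' or 'BH'")
  chk(cfg$centrality %in% c("kIM", "kME"), "centrality must be 'kIM' or 'kME'")
  chk(is.numeric(cfg$top_k) && cfg$top_k >= 1, "top_k must be a positive count")
  chk(is.numeric(cfg$mic_alpha) && cfg$mic_alpha > 0 && cfg$mic_alpha <= 1,
      "mic_alpha in (0,1]")
  chk(is.numeric(cfg$mic_c) && cfg$mic_c >= 1, "mic_c >= 1")
  chk(is.numeric(cfg$seed) && cfg$seed == as.integer(cfg$seed), "seed must be an integer")
  cfg
}

#' Build a run configuration
#'
#' All tunables of the pipeline stages with their defaults. Unknown names are
#' rejected.
#'
#' @param ... Named overrides of the defaults (see Details).
#' @details Fields: `normalization` ("quantile"/"none"), `filter_top_n`,
#'   `probe_collapse`, `powers`, `r2_cut`, `signed`, `cut_height`,
#'   `min_module_size`, `merge_dissimilarity`, `trait_method`, `p_adjust`,
#'   `centrality` ("kIM"/"kME"), `top_k`, `mic_alpha`, `mic_c`, `seed`.
#' @return A validated list of class `coex_config`.
#' @export
#' @examples
#' coex_config(cut_height = 0.9, seed = 42)
coex_config <- function(...) {
  over <- list(...)
  defaults <- .config_defaults()
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, over, keep.null = TRUE)
  cfg <- .validate_config(cfg)
  structure(cfg, class = "coex_config")
}

#' Read a run configuration from a YAML file
#'
#' Flat key-value YAML; keys must be known config fields. Unknown keys are
#' dropped with a warning; every retained field is validated.
#'
#' @param path Path to the YAML file.
#' @return A `coex_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(.config_defaults())
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warn(sprintf("unknown config key(s) ignored: %s", paste(unknown, collapse = ", ")))
    raw <- raw[intersect(names(raw), known)]
  }
  do.call(coex_config, raw)
}

#' Write a run configuration to YAML
#'
#' @param cfg A `coex_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
#' @method print coex_config
print.coex_config <- function(x, ...) {
  cat("<coex_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}
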