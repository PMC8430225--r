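#' @importFrom stats cor cor.test pt pchisq pnorm p.adjust rnorm rexp runif
#'   setNames var sd lm coef vcov
#' @importFrom utils read.table write.table head modifyList combn
NULL

# Internal: stop with a consistent error class so tests can assert on it.
lnc_stop <- function(msg, class = "lncnet_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

lnc_validation_error <- function(msg) lnc_stop(msg, "lncnet_validation_error")

# Internal: conditional progress/info messages (off by default in tests).
lnc_log <- function(...) {
  if (isTRUE(getOption("lncnet.verbose", FALSE))) message("[lncnet] ", ...)
}

#' Derive a reproducible sub-stream seed
#'
#' One global integer seed drives every generator in the package; each
#' generator draws from its own named sub-stream so that adding or reordering
#' generators never perturbs the others. The sub-stream seed is a
#' deterministic hash of `(seed, stream)` kept below `2^31`.
#'
#' @param seed Integer master seed.
#' @param stream Character name of the sub-stream (e.g. `"expression"`).
#' @return A single integer usable with [set.seed()].
#' @export
#' @examples
#' stream_seed(1, "expression")
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 1000003
  v <- ((abs(seed) %% 1000003) * 2039 + h * 7919) %% 2147483646
  as.integer(v) + 1L
}

with_stream_seed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, stream))
  expr
}

#' Default analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one list. Defaults
#' follow the published protocol where it states a value (PCC > 0.6 with
#' p < 0.01 for ceRNA calling, motif p < 1e-4, zero-expression fraction 0.7,
#' top 10% hubs, 1,000 permutations, promoter flank 2,000 bp, m6A PCC 0.6,
#' key-gene degree > 2) and conventional values where it does not
#' (hypergeometric p < 0.05, enhancer assignment within 100 kb).
#'
#' @param ... Named overrides of individual fields.
#' @return A list of class `lncnet_config`.
#' @export
#' @examples
#' cfg <- default_config(n_permutations = 200)
#' cfg$pcc_cutoff
default_config <- function(...) {
  cfg <- list(
    pcc_cutoff = 0.6,
    pcc_p_cutoff = 0.01,
    hyper_p_cutoff = 0.05,
    motif_p_cutoff = 1e-4,
    zero_fraction = 0.7,
    hub_fraction = 0.10,
    m6a_pcc_cutoff = 0.6,
    key_gene_min_degree = 3,
    n_permutations = 1000,
    promoter_flank = 2000,
    enhancer_max_dist = 100000,
    rng_seed = 1L,
    permutation_scheme = "gnm"
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) lnc_validation_error(paste0(
      "unknown config field(s): ", paste(bad, collapse = ", ")))
    cfg <- modifyList(cfg, over)
  }
  validate_config(cfg)
}

#' @rdname default_config
#' @param config A configuration list to validate.
#' @export
validate_config <- function(config) {
  in01 <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  if (!in01(config$pcc_cutoff) || !in01(config$pcc_p_cutoff) ||
      !in01(config$hyper_p_cutoff) || !in01(config$motif_p_cutoff) ||
      !in01(config$zero_fraction) || !in01(config$hub_fraction) ||
      !in01(config$m6a_pcc_cutoff))
    lnc_validation_error("config probability/fraction cutoffs must lie in [0,1]")
  if (config$n_permutations < 1) lnc_validation_error("n_permutations must be >= 1")
  if (config$promoter_flank <= 0) lnc_validation_error("promoter_flank must be > 0")
  if (config$enhancer_max_dist <= config$promoter_flank)
    lnc_validation_error("enhancer_max_dist must exceed promoter_flank")
  if (!config$permutation_scheme %in% c("gnm", "degree_preserving"))
    lnc_validation_error("permutation_scheme must be 'gnm' or 'degree_preserving'")
  class(config) <- "lncnet_config"
  config
}

#' Read / write a run configuration (YAML or JSON)
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return For `read_config`, a validated `lncnet_config` list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    lnc_stop(paste0("unsupported config format: .", ext)))
  do.call(default_config, raw)
}

#' @rdname read_config
#' @param config An `lncnet_config` list.
#' @export
write_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  x <- unclass(config)
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(x, path),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    lnc_stop(paste0("unsupported config format: .", ext)))
  invisible(path)
}
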