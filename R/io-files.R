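#' Write and read the event log as TSV
#'
#' Columns: \code{seq}, \code{time}, \code{kind}, \code{lineage_id},
#' \code{species_id}, \code{new_species_id}, \code{label}.  Times are
#' written with 15 significant digits so summary values reload losslessly.
#'
#' @param result An \code{"esm_sim"} object.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_event_log <- function(result, path) {
  stopifnot(inherits(result, "esm_sim"))
  ev <- result$events
  ev$time <- sprintf("%.15g", ev$time)
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "")
  need <- c("seq", "time", "kind", "lineage_id", "species_id",
            "new_species_id", "label")
  if (!all(need %in% names(ev)))
    stop("event log is missing columns: ",
         paste(setdiff(need, names(ev)), collapse = ", "))
  ev$label <- as.character(ev$label)
  ev$new_species_id <- as.integer(ev$new_species_id)
  ev[need]
}

#' Write the metadata sidecar for a simulation
#'
#' JSON with the resolved parameters, model, seed, survival flag, final
#' counts and the package version.
#'
#' @param result An \code{"esm_sim"} object.
#' @param path Output JSON path.
#' @param extra Optional named list merged into the record.
#' @return \code{path}, invisibly.
#' @export
write_sim_metadata <- function(result, path, extra = NULL) {
  stopifnot(inherits(result, "esm_sim"))
  p <- result$params
  meta <- list(
    package = "ephemsim",
    version = as.character(utils::packageVersion("ephemsim")),
    model = result$model,
    params = p[setdiff(names(p), "seed")],
    seed = p$seed,
    surviving = result$surviving,
    n_alive_final = result$n_alive_final,
    n_species_extant = result$n_species_extant,
    n_events = nrow(result$events),
    capped = result$capped,
    horizon = result$horizon)
  if (!is.null(extra)) meta <- c(meta, extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a simulation run configuration
#'
#' JSON or YAML (by extension) with keys \code{model}
#' (\code{"ephemeral"} or \code{"bd"}), the matching rate parameters
#' (\code{lambda_i}, \code{mu_i}, \code{lambda_f} or \code{lambda},
#' \code{mu}), \code{t_max}, \code{max_lineages}, \code{seed},
#' \code{replicates} and \code{condition_on_survival}.  The packaged
#' default configuration (\code{system.file("extdata",
#' "default_config.yaml", package = "ephemsim")}) keeps
#' \code{lambda_i/lambda_f} in the 30--40x regime reported for
#' subspeciation relative to speciation.
#'
#' @param path Path to a .json, .yaml or .yml file.
#' @return A validated list of class \code{"esm_config"} with elements
#'   \code{model}, \code{params} (an [esm_params()] or [bd_params()]),
#'   \code{replicates}, \code{condition_on_survival}, \code{output_dir}.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("config must be .json, .yaml or .yml"))
  as_config(raw)
}

as_config <- function(raw) {
  model <- raw$model %||% "ephemeral"
  if (!model %in% c("ephemeral", "bd"))
    stop("config 'model' must be \"ephemeral\" or \"bd\"")
  seed <- raw$seed
  t_max <- raw$t_max %||% 10
  cap <- raw$max_lineages %||% 50000L
  params <- if (model == "ephemeral") {
    esm_params(lambda_i = raw$lambda_i %||% 1.0,
               mu_i = raw$mu_i %||% 0.5,
               lambda_f = raw$lambda_f %||% 0.03,
               t_max = t_max, max_lineages = cap, seed = seed)
  } else {
    if (!is.null(raw$lambda_i) || !is.null(raw$lambda_f))
      stop("config: bd model takes 'lambda'/'mu', not lambda_i/lambda_f")
    bd_params(lambda = raw$lambda %||% 1.0, mu = raw$mu %||% 0.5,
              t_max = t_max, max_lineages = cap, seed = seed)
  }
  reps <- as.integer(raw$replicates %||% 1L)
  if (is.na(reps) || reps < 1L) stop("config 'replicates' must be >= 1")
  structure(list(
    model = model,
    params = params,
    replicates = reps,
    condition_on_survival = isTRUE(raw$condition_on_survival),
    output_dir = raw$output_dir %||% "ephemsim-output"),
    class = "esm_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a batch of simulations and write per-replicate files
#'
#' Replicate \code{r} is seeded with \code{seed + r}, so each replicate
#' depends only on \code{(seed, r)} and never on execution order.  For each
#' replicate the lineage genealogy and species tree (annotated Newick), the
#' event log (TSV) and a metadata sidecar (JSON) are written, named by
#' zero-padded replicate index.
#'
#' @param config An \code{"esm_config"} from [read_config()] or
#'   [as_config()].
#' @param output_dir Overrides the configured output directory.
#' @return Invisibly, the list of per-replicate results.
#' @export
run_batch <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "esm_config"))
  dir_out <- output_dir %||% config$output_dir
  dir.create(dir_out, showWarnings = FALSE, recursive = TRUE)
  base_seed <- config$params$seed
  simfun <- if (config$model == "bd") simulate_bd else simulate_esm
  results <- vector("list", config$replicates)
  wd <- nchar(as.character(config$replicates))
  for (r in seq_len(config$replicates)) {
    p <- config$params
    p$seed <- if (is.null(base_seed)) NULL else base_seed + r
    res <- if (config$condition_on_survival)
      condition_on_survival(p) else simfun(p)
    tag <- formatC(r, width = max(4L, wd), flag = "0")
    write_newick(lineage_phylo(res),
                 file.path(dir_out, sprintf("rep_%s_lineage.nwk", tag)))
    if (res$surviving || res$model == "bd") {
      st <- tryCatch(collapse_to_species_tree(res), error = function(e) NULL)
      if (!is.null(st))
        write_newick(st,
                     file.path(dir_out, sprintf("rep_%s_species.nwk", tag)))
    }
    write_event_log(res, file.path(dir_out, sprintf("rep_%s_events.tsv", tag)))
    write_sim_metadata(res, file.path(dir_out, sprintf("rep_%s_meta.json", tag)),
                       extra = list(replicate = r))
    results[[r]] <- res
  }
  invisible(results)
}
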