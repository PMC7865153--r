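# Readers and writers: two-column trace text, JSON containers for networks,
# datasets and descrambler results, YAML run configuration.

#' Read a DEER trace from two-column text
#'
#' Whitespace- or comma-delimited text, column 1 time in microseconds,
#' column 2 amplitude; lines starting with '#' are ignored. The time column
#' must start at 0 and be uniform to 1e-6 relative.
#'
#' @param path file path.
#' @return A [deer_trace()] (kind `noisy`) on the file's [time_grid()].
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (!length(rows)) stop("no data rows in ", path)
  parse_row <- function(i) {
    parts <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) < 2 || any(is.na(vals[1:2]))) {
      stop("non-numeric row at line ", i, " of ", path)
    }
    vals[1:2]
  }
  m <- t(vapply(rows, parse_row, numeric(2)))
  tt <- m[, 1]; v <- m[, 2]
  if (length(tt) < 2) stop("need at least two samples in ", path)
  dt <- diff(tt)
  bad <- which(abs(dt - dt[1]) > 1e-6 * max(abs(dt[1]), 1e-300))
  if (length(bad)) {
    stop("non-uniform time grid at line ", rows[bad[1] + 1], " of ", path)
  }
  if (abs(tt[1]) > 1e-12 * max(abs(tt))) stop("time grid must start at 0 in ", path)
  deer_trace(v, time_grid(tt[length(tt)], length(tt)), kind = "noisy")
}

#' Write a DEER trace as two-column text
#'
#' @param trace a [deer_trace()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "deer_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# DEER trace: time (us), amplitude",
               sprintf("%.17g %.17g", trace$grid$t, trace$values)), con)
  invisible(path)
}

#' Save and load a network as a JSON container
#'
#' Weight matrices, biases, activation tags and any stored descrambling
#' transforms, at full double precision so the round trip is exact.
#'
#' @param net a `fredholm_net`.
#' @param path file path.
#' @return `path` (save) or the restored `fredholm_net` (load).
#' @export
save_network <- function(net, path) {
  payload <- list(
    weights = lapply(net$weights, unclass),
    biases = net$biases,
    activations = net$activations,
    input_width = net$input_width,
    target_scale = net$target_scale,
    loss_history = net$loss_history,
    pre_act = net$pre_act,
    post_act = net$post_act,
    output_undo = net$output_undo
  )
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)
  nl <- length(p$activations)
  fix_list <- function(z) {
    # a list of all-nulls may come back simplified to an atomic NA vector
    if (is.null(z) || length(z) == 0 || (is.atomic(z) && all(is.na(z)))) {
      return(vector("list", nl))
    }
    lapply(z, function(e) {
      if (is.null(e) || !length(e) || (is.atomic(e) && all(is.na(e)))) NULL
      else as_mat(e)
    })
  }
  net <- structure(list(
    weights = lapply(p$weights, as_mat),
    biases = lapply(p$biases, as.numeric),
    activations = as.character(p$activations),
    pre_act = fix_list(p$pre_act),
    post_act = fix_list(p$post_act),
    input_width = as.integer(p$input_width),
    target_scale = as.numeric(p$target_scale),
    loss_history = as.numeric(p$loss_history)
  ), class = "fredholm_net")
  if (!is.null(p$output_undo) && length(p$output_undo)) {
    net$output_undo <- as_mat(p$output_undo)
  }
  validate_net(net)
}

#' Save and load a dataset as JSON + TSV containers
#'
#' `<stem>.json` holds the grids, seed and per-record nuisance parameters;
#' `<stem>_inputs.tsv` and `<stem>_targets.tsv` hold the matrices.
#'
#' @param dataset a `deer_dataset`.
#' @param stem path stem (no extension).
#' @return `stem` (save) or the restored `deer_dataset` (load).
#' @export
save_dataset <- function(dataset, stem) {
  meta <- list(
    tgrid = list(t_max = dataset$tgrid$t_max, n = dataset$tgrid$n),
    dgrid = list(r_min = dataset$dgrid$r_min, r_max = dataset$dgrid$r_max,
                 n = dataset$dgrid$n),
    seed = dataset$seed,
    records = dataset$records
  )
  jsonlite::write_json(meta, paste0(stem, ".json"), digits = I(17), auto_unbox = TRUE)
  utils::write.table(dataset$inputs, paste0(stem, "_inputs.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(dataset$targets, paste0(stem, "_targets.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(stem)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  inputs <- as.matrix(utils::read.table(paste0(stem, "_inputs.tsv"), sep = "\t"))
  targets <- as.matrix(utils::read.table(paste0(stem, "_targets.tsv"), sep = "\t"))
  dimnames(inputs) <- dimnames(targets) <- NULL
  records <- if (is.data.frame(meta$records)) {
    lapply(seq_len(nrow(meta$records)), function(i) as.list(meta$records[i, ]))
  } else meta$records
  structure(list(inputs = inputs, targets = targets, records = records,
                 dgrid = distance_grid(meta$dgrid$r_min, meta$dgrid$r_max, meta$dgrid$n),
                 tgrid = time_grid(meta$tgrid$t_max, meta$tgrid$n),
                 seed = meta$seed),
            class = "deer_dataset")
}

#' Default run configuration
#'
#' All stage parameters of a full workflow in one structured list that
#' round-trips losslessly through YAML. Every stochastic stage derives its
#' seed deterministically from `master_seed` and the stage name.
#'
#' @param scale `"small"` (64-point grids, 32-wide link) or `"full"`
#'   (256-point grids, 80-wide reduced link).
#' @param master_seed integer master seed.
#' @param output_dir artifact directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(scale = c("small", "full"), master_seed = 1L,
                       output_dir = "descrambler-run") {
  scale <- match.arg(scale)
  small <- scale == "small"
  structure(list(
    scale = scale,
    master_seed = as.integer(master_seed),
    output_dir = output_dir,
    grids = list(t_max = 3.2, n_time = if (small) 64L else 256L,
                 r_min = 1.5, r_max = 8, n_dist = if (small) 64L else 256L),
    dataset = c(list(n_records = if (small) 5000L else 20000L), synthetic_config()),
    training = list(hidden_width = if (small) 32L else 256L,
                    epochs = if (small) 600L else 300L, batch_size = 100L,
                    learning_rate = 2e-3, val_fraction = 0.1),
    descrambler = list(layer = 1L, tap = "before_activation",
                       objective = "tikhonov", link_weight = 1,
                       tol = 1e-8, maxiter = if (small) 2000L else 500L),
    replica = list(n_pairs = 2000L,
                   filters = default_filter_specs(if (small) "small" else "full"))
  ), class = "run_config")
}

stage_seed_salt <- c(simulate = 101L, train = 211L, descramble = 307L,
                     interpret = 401L, replica = 503L, report = 601L)

#' Stage seed derived from the master seed
#'
#' @param config a [run_config()].
#' @param stage stage name.
#' @return integer seed below 2^31.
#' @export
stage_seed <- function(config, stage) {
  if (!stage %in% names(stage_seed_salt)) stop("unknown stage: ", stage)
  salt <- stage_seed_salt[[stage]]
  derive_seed(config$master_seed, salt)
}

#' Write and read a run configuration
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `path` (write) or the restored `run_config` (read).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$master_seed <- as.integer(cfg$master_seed)
  for (nm in c("n_time", "n_dist")) cfg$grids[[nm]] <- as.integer(cfg$grids[[nm]])
  cfg$dataset$n_records <- as.integer(cfg$dataset$n_records)
  cfg$replica$filters <- lapply(cfg$replica$filters, function(sp)
    fir_filter_spec(sp$kind, sp$order, sp$passband_edge, sp$stopband_edge))
  structure(cfg, class = "run_config")
}
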