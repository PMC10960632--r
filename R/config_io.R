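#' Write / read a pipeline configuration as JSON
#'
#' Lossless serialisation of a [pipeline_config()] (including its nested
#' [design_spec()] and [memory_model()]), so a run can be reproduced from
#' the configuration file and master seed alone.
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return (invisibly) the path; `read_pipeline_config` returns the
#'   reconstructed `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  obj <- unclass(config)
  obj$group_acat <- as.list(obj$group_acat)
  obj$group_bitem <- as.list(obj$group_bitem)
  obj$design <- unclass(obj$design)
  obj$memory <- if (is.null(obj$memory)) NULL else unclass(obj$memory)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  design <- do.call(design_spec, c(
    obj$design[setdiff(names(obj$design), "retrieval_counts")],
    list(retrieval_counts = as.list(obj$design$retrieval_counts))))
  memory <- if (is.null(obj$memory)) NULL else
    do.call(memory_model, obj$memory)
  pipeline_config(
    n_young = obj$n_young, n_old = obj$n_old, design = design,
    grid_shape = obj$grid_shape, signal_region = obj$signal_region,
    group_acat = unlist(obj$group_acat),
    group_bitem = unlist(obj$group_bitem), memory = memory,
    radius_mm = obj$radius_mm, voxel_size_mm = obj$voxel_size_mm,
    min_voxels = obj$min_voxels, alpha = obj$alpha,
    min_size = obj$min_size, connectivity = obj$connectivity,
    n_perm = obj$n_perm, n_perm_plsc = obj$n_perm_plsc,
    n_boot_plsc = obj$n_boot_plsc,
    do_memory_split = obj$do_memory_split, seed = obj$seed)
}
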