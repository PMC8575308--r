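# On-disk formats.  Every writer emits a format_version field.  Numeric
# payload goes into a plain-text array container at "%.17g" precision, which
# round-trips IEEE doubles exactly; the JSON header stores structure and
# scalars (scalars likewise as %.17g strings so reload is bit-identical).

FORMAT_VERSION <- 1L

num_chr <- function(x) sprintf("%.17g", as.numeric(x))

arrays_path_for <- function(path) {
  sub("\\.json$", ".arrays.tsv", path)
}

write_arrays <- function(arrays, path) {
  rows <- lapply(names(arrays), function(nm) {
    data.frame(name = nm, value = num_chr(arrays[[nm]]))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

read_arrays <- function(path) {
  df <- read.delim(path, colClasses = c("character", "character"))
  split_vals <- split(as.numeric(df$value), df$name)
  split_vals
}

#' Save a spatial GLV system
#'
#' Writes a JSON header (sizes, ensemble parameters, geometry, seeds,
#' format/package version) alongside `<path minus .json>.arrays.tsv` holding
#' the interaction matrix `A` (column-major) and the diffusion-rate, growth
#' and carrying-capacity vectors at full precision.  [read_system()] restores
#' the system bit-identically.
#'
#' @param system a [build_system()] result.
#' @param path output path ending in `.json`.
#' @return `path`, invisibly.
#' @export
write_system <- function(system, path) {
  stopifnot(inherits(system, "glv_system"), grepl("\\.json$", path))
  apath <- arrays_path_for(path)
  header <- list(
    format_version = FORMAT_VERSION,
    package = "metaglv",
    package_version = as.character(utils::packageVersion("metaglv")),
    kind = "glv_system",
    N = system$community$N,
    c = num_chr(system$community$c),
    mu = num_chr(system$community$mu),
    sigma = num_chr(system$community$sigma),
    mu_D = num_chr(system$dispersal$mu_D),
    b = num_chr(system$dispersal$b),
    geometry = list(ndim = system$geometry$ndim,
                    extent = system$geometry$extent,
                    h = num_chr(system$geometry$h)),
    seed = system$seed,
    sub_seeds = as.list(system$sub_seeds),
    arrays_file = basename(apath)
  )
  jsonlite::write_json(header, path, auto_unbox = TRUE, pretty = TRUE)
  write_arrays(list(A = system$community$A, D = system$dispersal$D,
                    r = system$community$r, K = system$community$K), apath)
  invisible(path)
}

#' Load a spatial GLV system saved with [write_system()]
#'
#' @param path path to the `.json` header.
#' @return a `glv_system`.
#' @export
read_system <- function(path) {
  header <- jsonlite::read_json(path)
  if (!identical(header$kind, "glv_system")) {
    stop("not a glv_system file", call. = FALSE)
  }
  arrays <- read_arrays(file.path(dirname(path), header$arrays_file))
  N <- header$N
  A <- matrix(arrays$A, N, N)
  geom <- grid_geometry(header$geometry$ndim,
                        unlist(header$geometry$extent),
                        as.numeric(header$geometry$h))
  structure(
    list(
      community = community(A, sigma = as.numeric(header$sigma),
                            r = arrays$r, K = arrays$K,
                            c = as.numeric(header$c),
                            mu = as.numeric(header$mu)),
      dispersal = dispersal_profile(arrays$D, as.numeric(header$mu_D),
                                    as.numeric(header$b)),
      geometry = geom,
      seed = as.integer(header$seed),
      sub_seeds = setNames(as.integer(unlist(header$sub_seeds)),
                           names(header$sub_seeds))
    ),
    class = "glv_system"
  )
}

#' Save a trajectory
#'
#' JSON header (shape, solver metadata) plus the array container holding the
#' time grid and the abundance array (flattened in `(time, grid-point,
#' species)` order).  Loading restores the trajectory exactly.
#'
#' @param trajectory a `glv_trajectory`.
#' @param path output path ending in `.json`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "glv_trajectory"), grepl("\\.json$", path))
  apath <- arrays_path_for(path)
  d <- dim(trajectory$phi)
  header <- list(
    format_version = FORMAT_VERSION,
    kind = "glv_trajectory",
    dim = d,
    diverged = isTRUE(trajectory$diverged),
    geometry = list(ndim = trajectory$geometry$ndim,
                    extent = trajectory$geometry$extent,
                    h = num_chr(trajectory$geometry$h)),
    solver = lapply(trajectory$solver, num_chr),
    arrays_file = basename(apath)
  )
  jsonlite::write_json(header, path, auto_unbox = TRUE, pretty = TRUE)
  write_arrays(list(times = trajectory$times,
                    phi = as.numeric(trajectory$phi)), apath)
  invisible(path)
}

#' Load a trajectory saved with [write_trajectory()]
#'
#' @param path path to the `.json` header.
#' @return a `glv_trajectory` (without the originating `system`).
#' @export
read_trajectory <- function(path) {
  header <- jsonlite::read_json(path)
  if (!identical(header$kind, "glv_trajectory")) {
    stop("not a glv_trajectory file", call. = FALSE)
  }
  arrays <- read_arrays(file.path(dirname(path), header$arrays_file))
  d <- unlist(header$dim)
  structure(
    list(times = arrays$times,
         phi = array(arrays$phi, dim = d),
         geometry = grid_geometry(header$geometry$ndim,
                                  unlist(header$geometry$extent),
                                  as.numeric(header$geometry$h)),
         system = NULL,
         diverged = isTRUE(header$diverged),
         solver = lapply(header$solver, as.numeric)),
    class = "glv_trajectory"
  )
}

#' Serialise a run summary to one JSON record
#'
#' @param summary a `glv_run_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  stopifnot(inherits(summary, "glv_run_summary"))
  rec <- unclass(summary)
  rec$format_version <- FORMAT_VERSION
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Serialise a regime report to JSON
#'
#' @param report a `glv_regime_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regime_report <- function(report, path) {
  stopifnot(inherits(report, "glv_regime_report"))
  rec <- unclass(report)
  rec$format_version <- FORMAT_VERSION
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", dataframe = "rows")
  invisible(path)
}
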