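#' Save a trained model or agent to disk
#'
#' Serializes the object with a package-version tag; the round trip is
#' bit-exact, so projections of a reloaded model reproduce the original to
#' the last bit.
#'
#' @param object any slowrl model object (e.g. an [sfa_hierarchy()]).
#' @param path destination file path.
#' @export
save_model <- function(object, path) {
  saveRDS(list(format = "slowrl-model", version = 1L,
               package = as.character(utils::packageVersion("slowrl")),
               object = object),
          path)
  invisible(path)
}

#' Load a model saved with [save_model()]
#' @param path file path.
#' @return the stored object.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tryCatch(readRDS(path),
                error = function(e) stop("cannot read model container '",
                                         path, "': ", conditionMessage(e)))
  if (!is.list(x) || !identical(x$format, "slowrl-model")) {
    stop("'", path, "' is not a slowrl model container")
  }
  if (!identical(x$version, 1L)) {
    stop("unsupported model container version: ", x$version)
  }
  x$object
}

## constructors reachable from YAML configs, with their value checks
config_constructors <- function() {
  list(world = world_config, task = task_config,
       hierarchy = hierarchy_config)
}

#' Load a validated configuration tree from YAML
#'
#' Each top-level section (\code{world}, \code{task}, \code{hierarchy}) is
#' passed through the corresponding constructor, so defaults are filled in
#' and invalid values are rejected with the offending section and field
#' named.
#'
#' @param path YAML file path.
#' @return named list of validated configuration objects.
#' @seealso [save_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- yaml::read_yaml(path)
  out <- list()
  for (section in names(raw)) {
    ctor <- config_constructors()[[section]]
    if (is.null(ctor)) stop("unknown config section '", section, "'")
    args <- raw[[section]]
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad) > 0L) {
      stop("config section '", section, "': unknown field(s) ",
           paste0("'", bad, "'", collapse = ", "))
    }
    out[[section]] <- tryCatch(
      do.call(ctor, args),
      error = function(e) stop("config section '", section, "': ",
                               conditionMessage(e)))
  }
  out
}

#' Write configuration objects to YAML
#' @param config named list of configuration objects (as from
#'   [load_config()]).
#' @param path destination path.
#' @export
save_config <- function(config, path) {
  strip <- function(x) {
    if (inherits(x, "node_spec")) return(unclass(x))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  yaml::write_yaml(lapply(config, strip), path)
  invisible(path)
}

#' Tiny deterministic image streams for tests and demos
#'
#' Small-resolution streams generated by the package's own environment:
#' \code{"watermaze"} and \code{"variable_targets"} use the standard
#' random walk at a reduced resolution; \code{"single_latent"} renders a
#' disk whose only slowly varying latent is its x-position (a sinusoidal
#' sweep), with the latent attached for recovery tests.
#'
#' @param kind stream kind.
#' @param n number of frames.
#' @param seed integer seed.
#' @param resolution image side in pixels.
#' @return an \code{n} x \code{resolution^2} frame matrix with attribute
#'   \code{"latents"}.
#' @export
make_fixture_stream <- function(kind = c("watermaze", "variable_targets",
                                         "single_latent"),
                                n, seed = 1L, resolution = 24L) {
  kind <- match.arg(kind)
  if (kind == "single_latent") {
    cfg <- world_config(resolution = resolution, n_objects = 2L)
    g <- render_grid(cfg)
    xs <- 0.7 * sin(2 * pi * seq_len(n) / n)
    out <- matrix(0, n, resolution^2)
    for (t in seq_len(n)) {
      img <- disk_sprite(g$X, g$Y, c(xs[t], 0), 0.3, g$edge)
      out[t, ] <- as.vector(t(img))
    }
    attr(out, "latents") <- data.frame(x = xs, y = 0)
    return(out)
  }
  cfg <- world_config(resolution = resolution,
                      n_objects = if (kind == "watermaze") 0L else 2L)
  generate_training_stream(n, cfg, kind, seed = seed)
}
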