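#' Application configuration
#'
#' Collects the tunable constants of the routing model in one validated
#' object. The defaults encode the study conditions the model was designed
#' around: a fallback travel speed of 40 km/h for road segments without a
#' posted limit, a maximum traffic density of 100 vehicles per km where none
#' is supplied, and an operating saturation level of 0.70 for scenario
#' presets.
#'
#' @param formula_mode How congestion scales travel time. In
#'   `"greenshields_division"` (the default) the free-flow traversal time is
#'   divided by `1 - k/k_max`, so travel time grows as the segment fills. In
#'   `"as_printed"` the free-flow time is multiplied by `1 - k/k_max`.
#' @param default_speed_kmh Speed assigned to segments with no posted limit
#'   (km/h).
#' @param default_k_max Maximum traffic density assumed for segments that do
#'   not state one (vehicles per km).
#' @param saturation_clamp Upper bound applied to the saturation ratio
#'   `k/k_max` before use, keeping the division mode finite near jam density.
#' @param default_saturation Saturation ratio applied network-wide when a
#'   global congestion scenario is requested but edges carry no vehicle
#'   counts.
#' @param tie_rule Tie-breaking rule for equal costs; only
#'   `"lexicographic"` (smallest identifier wins, C-locale ordering) is
#'   supported.
#'
#' @return An object of class `catchroute_config` (a named list).
#' @examples
#' cfg <- app_config()
#' cfg$default_speed_kmh
#' @export
app_config <- function(formula_mode = c("greenshields_division", "as_printed"),
                       default_speed_kmh = 40,
                       default_k_max = 100,
                       saturation_clamp = 0.95,
                       default_saturation = 0.70,
                       tie_rule = "lexicographic") {
  formula_mode <- match.arg(formula_mode)
  if (!identical(tie_rule, "lexicographic")) {
    stop("tie_rule must be 'lexicographic'", call. = FALSE)
  }
  num <- c(default_speed_kmh = default_speed_kmh,
           default_k_max = default_k_max,
           saturation_clamp = saturation_clamp,
           default_saturation = default_saturation)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all numeric configuration values must be positive and finite",
         call. = FALSE)
  }
  if (saturation_clamp >= 1) {
    stop("saturation_clamp must be < 1 to keep congested travel time finite",
         call. = FALSE)
  }
  if (default_saturation > saturation_clamp) {
    stop("default_saturation must not exceed saturation_clamp", call. = FALSE)
  }
  structure(
    list(formula_mode = formula_mode,
         default_speed_kmh = default_speed_kmh,
         default_k_max = default_k_max,
         saturation_clamp = saturation_clamp,
         default_saturation = default_saturation,
         tie_rule = tie_rule),
    class = "catchroute_config"
  )
}

#' Read or write a configuration file
#'
#' Configurations are stored as plain YAML so they can be versioned and
#' diffed. Unknown keys are rejected rather than ignored.
#'
#' @param path File path.
#' @param config A [app_config()] object.
#' @return `read_config()` returns a `catchroute_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(app_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    stop("unknown configuration keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(app_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "catchroute_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.catchroute_config <- function(x, ...) {
  cat("<catchroute_config>\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
  invisible(x)
}
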