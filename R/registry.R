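#' The ISAW metric registry
#'
#' The Instrumented Stand and Walk (ISAW) test yields 17 balance and gait
#' metrics spanning seven mobility domains: postural sway in quiet stance
#' (`S`), the anticipatory postural adjustment preceding step initiation
#' (`A`), temporal (`G:T`), spatial (`G:S`), variability (`G:V`) and
#' upper-body (`G:U`) gait characteristics, and turning (`T`).  Four sway
#' metrics are right-skewed and are carried on the natural-log scale
#' throughout (generation, summaries, and modelling); `log_scale` flags
#' them.
#'
#' The registry is the single source of truth for metric names, domain
#' tags, units and analysis scale; all cohort columns are interpreted
#' through it.
#'
#' @return A data frame with one row per metric and columns `name`,
#'   `domain`, `log_scale`, `units`.
#' @seealso [isaw_group_params()] for the group-conditional means and SDs
#'   used by the synthetic cohort generator.
#' @export
#' @examples
#' isaw_metrics()
isaw_metrics <- function() {
  reg <- registry_fixture()
  data.frame(
    name = vapply(reg$metrics, `[[`, character(1), "name"),
    domain = vapply(reg$metrics, `[[`, character(1), "domain"),
    log_scale = vapply(reg$metrics, `[[`, logical(1), "log_scale"),
    units = vapply(reg$metrics, `[[`, character(1), "units"),
    stringsAsFactors = FALSE
  )
}

#' Group-conditional summary parameters for the 17 ISAW metrics
#'
#' Published group-level means and standard deviations of each ISAW metric
#' for prospective non-fallers (n = 123) and fallers (n = 91), on the
#' analysis scale (natural log for the four flagged sway metrics).  These
#' are the marginal targets the synthetic cohort generator reproduces.
#'
#' @return A data frame with one row per metric: `name`, `mean_nonfaller`,
#'   `sd_nonfaller`, `mean_faller`, `sd_faller`, plus attributes
#'   `n_nonfaller` and `n_faller` carrying the reference group sizes.
#' @export
isaw_group_params <- function() {
  reg <- registry_fixture()
  out <- data.frame(
    name = vapply(reg$metrics, `[[`, character(1), "name"),
    mean_nonfaller = vapply(reg$metrics, `[[`, numeric(1), "mean_nonfaller"),
    sd_nonfaller = vapply(reg$metrics, `[[`, numeric(1), "sd_nonfaller"),
    mean_faller = vapply(reg$metrics, `[[`, numeric(1), "mean_faller"),
    sd_faller = vapply(reg$metrics, `[[`, numeric(1), "sd_faller"),
    stringsAsFactors = FALSE
  )
  stopifnot(all(out$sd_nonfaller > 0), all(out$sd_faller > 0))
  attr(out, "n_nonfaller") <- reg$n_nonfaller
  attr(out, "n_faller") <- reg$n_faller
  out
}

# Parsed packaged registry, cached per session.
registry_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "isaw_registry.json", package = "fallbma",
                          mustWork = TRUE)
      cache <<- jsonlite::read_json(path)
    }
    cache
  }
})

#' Validate a metric registry
#'
#' @param registry A data frame as returned by [isaw_metrics()], or a
#'   character vector of metric names (minimal registry with no domain or
#'   scale metadata).
#' @return The registry as a validated data frame.
#' @keywords internal
as_registry <- function(registry) {
  if (is.character(registry)) {
    registry <- data.frame(name = registry,
                           domain = NA_character_,
                           log_scale = FALSE,
                           units = NA_character_,
                           stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(registry),
            all(c("name", "log_scale") %in% names(registry)))
  if (anyDuplicated(registry$name)) {
    stop("duplicate metric names in registry: ",
         paste(unique(registry$name[duplicated(registry$name)]), collapse = ", "))
  }
  registry
}
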