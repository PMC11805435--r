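#' Model specification
#'
#' Describes one of the four model types fitted and compared:
#' \describe{
#'   \item{glm}{fixed effects only, one dataset-species pair;}
#'   \item{car}{fixed effects plus a univariate Leroux CAR field on the
#'     flow network, one dataset-species pair;}
#'   \item{mcar_dt}{joint model of one species' survey and presence-only
#'     datasets with an MCAR prior correlating the two fields;}
#'   \item{mcar_sp}{joint model of two species' survey datasets with an
#'     MCAR prior.}
#' }
#'
#' @param model_type one of \code{"glm"}, \code{"car"},
#'   \code{"mcar_dt"}, \code{"mcar_sp"}.
#' @param species character vector of species ids (one for glm / car /
#'   mcar_dt, two for mcar_sp).
#' @param datasets character vector drawn from \code{c("survey", "po")}:
#'   one for glm / car, both for mcar_dt, \code{"survey"} for mcar_sp.
#' @param covariates subset of \code{c("log_NC", "MT")}.
#' @return list of class \code{model_spec}.
#' @export
model_spec <- function(model_type = c("glm", "car", "mcar_dt", "mcar_sp"),
                       species, datasets = "survey",
                       covariates = c("log_NC", "MT")) {
  model_type <- match.arg(model_type)
  stopifnot(all(datasets %in% c("survey", "po")),
            all(covariates %in% c("log_NC", "MT")))
  if (model_type %in% c("glm", "car")) {
    if (length(species) != 1L || length(datasets) != 1L)
      stop(model_type, " binds exactly one dataset-species pair")
  } else if (model_type == "mcar_dt") {
    if (length(species) != 1L ||
        !setequal(datasets, c("survey", "po")))
      stop("mcar_dt pairs one species' survey and presence-only datasets")
    datasets <- c("survey", "po")
  } else {
    if (length(species) != 2L || !identical(unique(datasets), "survey"))
      stop("mcar_sp pairs two species' survey datasets")
  }
  structure(list(model_type = model_type, species = species,
                 datasets = datasets, covariates = covariates),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", x$model_type,
      "| species:", paste(x$species, collapse = "+"),
      "| datasets:", paste(x$datasets, collapse = "+"),
      "| covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Assemble likelihood datasets for a model specification
#'
#' Turns a port-data object (see \code{\link{read_port_table}}) and a
#' \code{model_spec} into the list of likelihood datasets the sampler
#' consumes: for each dataset a family, response, trial counts and
#' design matrix (intercept column plus the selected covariates, with
#' species-specific log_NC).
#'
#' @param port_data object from \code{\link{read_port_table}} or
#'   \code{\link{simulate_dataset}}.
#' @param spec a \code{model_spec}.
#' @return list of dataset lists with elements \code{family}, \code{y},
#'   \code{n}, \code{X}, \code{label}.
#' @export
build_datasets <- function(port_data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  cov <- port_data$covariates
  design_for <- function(sp) {
    X <- NULL
    if ("log_NC" %in% spec$covariates) {
      lnc <- cov$log_nc
      col <- if (is.matrix(lnc) && !is.null(colnames(lnc)))
        lnc[, sp] else as.numeric(lnc)
      X <- cbind(X, log_NC = col)
    }
    if ("MT" %in% spec$covariates) X <- cbind(X, MT = cov$mt)
    if (is.null(X)) X <- matrix(nrow = length(port_data$roster), ncol = 0)
    X
  }
  pairs <- switch(spec$model_type,
    glm = , car = list(list(sp = spec$species, ds = spec$datasets)),
    mcar_dt = list(list(sp = spec$species, ds = "survey"),
                   list(sp = spec$species, ds = "po")),
    mcar_sp = list(list(sp = spec$species[1], ds = "survey"),
                   list(sp = spec$species[2], ds = "survey"))
  )
  lapply(pairs, function(pr) {
    if (pr$ds == "survey") {
      list(family = "binomial",
           y = port_data$det[, pr$sp],
           n = port_data$n_surveys,
           X = design_for(pr$sp),
           label = paste0("survey_", pr$sp))
    } else {
      list(family = "poisson",
           y = port_data$po[, pr$sp],
           n = NULL,
           X = design_for(pr$sp),
           label = paste0("po_", pr$sp))
    }
  })
}
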