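#' Read a YAML configuration file
#'
#' Configuration blocks understood by the package:
#' \describe{
#'   \item{template}{\code{peptide_chain}, \code{ligand_codes},
#'     \code{receptor_chains}, and \code{anchors} with \code{q_alpha},
#'     \code{r_beta}, \code{zn_triad_1..3} as \code{"chain:resno:atom"}.}
#'   \item{energy}{\code{weights} overriding any energy term weight.}
#'   \item{constraints}{\code{sd} (Angstrom, default 0.1).}
#'   \item{minimize}{\code{tolerance} (default 0.0001), \code{max_iter},
#'     \code{interface_cutoff} (default 8.0).}
#'   \item{classify}{\code{loose} and \code{stringent} thresholds.}
#' }
#'
#' @param path YAML file path.
#' @return nested named list.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  yaml::read_yaml(path)
}

#' Prepare a template as described by a configuration
#'
#' @param structure a \linkS4class{Structure}.
#' @param config list from \code{\link{readConfig}} (its \code{template}
#'   block is used).
#' @return a \linkS4class{TemplateComplex}.
#' @export
templateFromConfig <- function(structure, config) {
  tc <- config$template
  if (is.null(tc)) stop("configuration lacks a 'template' block")
  prepareTemplate(structure,
                  peptideChain = tc$peptide_chain,
                  ligandCodes = as.character(tc$ligand_codes %||% character()),
                  receptorChains = tc$receptor_chains,
                  anchorConfig = tc$anchors)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build an energy function from a configuration
#'
#' @param config list from \code{\link{readConfig}}.
#' @return an \linkS4class{EnergyFunction}.
#' @export
energyFromConfig <- function(config) {
  w <- config$energy$weights
  defaultEnergyFunction(weights = if (is.null(w)) NULL else unlist(w))
}

#' Build a classifier configuration from a configuration list
#'
#' @param config list from \code{\link{readConfig}}.
#' @return a \linkS4class{ClassifierConfig}.
#' @export
classifierFromConfig <- function(config) {
  classifierConfig(loose = config$classify$loose %||% -0.4,
                   stringent = config$classify$stringent %||% -1.1)
}
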