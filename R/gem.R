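## Genome-scale metabolic model (GEM) container and readers.
##
## A GEM is a stoichiometric matrix S (metabolites x reactions) with flux
## bounds, an objective (the biomass reaction) and a registry of exchange
## reactions (single-metabolite boundary reactions; negative flux is
## uptake, the standard fbc sign convention).

#' Construct a genome-scale metabolic model
#'
#' @param S Stoichiometric matrix (metabolites x reactions), dimnames set.
#' @param lb,ub Flux bounds per reaction (mmol/gDW/h). `lb <= ub` required;
#'   infinite bounds are permitted and boxed at +/- 1000 when solving.
#' @param obj Objective coefficients per reaction; at least one non-zero
#'   (the biomass reaction).
#' @param id Model identifier.
#' @return An object of class `gem`.
#' @export
gem <- function(S, lb, ub, obj, id = "model") {
  S <- as.matrix(S)
  nr <- ncol(S)
  if (is.null(rownames(S)) || is.null(colnames(S)))
    stop_bad_arg("S needs metabolite rownames and reaction colnames")
  if (length(lb) != nr || length(ub) != nr || length(obj) != nr)
    stop_bad_arg("bounds/objective length must equal the number of reactions")
  lb <- as.numeric(lb); ub <- as.numeric(ub); obj <- as.numeric(obj)
  if (any(lb > ub)) {
    bad <- colnames(S)[lb > ub]
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (all(obj == 0)) stop("model has no objective reaction", call. = FALSE)
  names(lb) <- names(ub) <- names(obj) <- colnames(S)
  nz <- colSums(S != 0)
  exch <- colnames(S)[nz == 1L]
  ex_met <- vapply(exch, function(r) rownames(S)[which(S[, r] != 0)], "")
  structure(list(id = id, metabolites = rownames(S),
                 reactions = colnames(S), S = S, lb = lb, ub = ub,
                 obj = obj, exchanges = ex_met,
                 objective_id = colnames(S)[which(obj != 0)[1]]),
            class = "gem")
}

#' @export
print.gem <- function(x, ...) {
  cat("<gem>", x$id, "|", length(x$metabolites), "metabolites,",
      length(x$reactions), "reactions (", length(x$exchanges), "exchange )\n")
  cat("  objective:", x$objective_id, "\n")
  invisible(x)
}

#' Load a genome-scale metabolic model from JSON or SBML
#'
#' JSON follows the common constraint-based schema (`metabolites` and
#' `reactions` arrays; each reaction has a `metabolites` mapping,
#' `lower_bound`, `upper_bound` and `objective_coefficient`). SBML Level 3
#' with the `fbc` package is supported for species, reactions,
#' stoichiometry, flux-bound parameters and the active objective; other
#' constructs are ignored with a warning.
#'
#' @param path File path.
#' @param format `"json"`, `"sbml"`, or `NULL` to guess from the extension.
#' @return A [gem()].
#' @export
load_gem <- function(path, format = NULL) {
  if (!file.exists(path)) stop_bad_arg("no such file: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "json", xml = "sbml", sbml = "sbml",
                     stop_bad_arg("cannot guess model format from '", path, "'"))
  }
  switch(match.arg(format, c("json", "sbml")),
         json = read_gem_json(path),
         sbml = read_gem_sbml(path))
}

read_gem_json <- function(path) {
  doc <- jsonlite::read_json(path)
  mets <- vapply(doc$metabolites, function(m)
    if (is.list(m)) m$id else as.character(m), "")
  rxns <- vapply(doc$reactions, `[[`, "", "id")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  bad <- character(0)
  for (r in doc$reactions) {
    st <- unlist(r$metabolites)
    unknown <- setdiff(names(st), mets)
    if (length(unknown)) { bad <- c(bad, r$id); next }
    S[names(st), r$id] <- as.numeric(st)
  }
  if (length(bad))
    stop("inconsistent stoichiometry (unknown metabolites) in reaction(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  num_or <- function(r, field, default) {
    v <- r[[field]]
    if (is.null(v)) default else as.numeric(v)
  }
  lb <- vapply(doc$reactions, num_or, 0, field = "lower_bound", default = -1000)
  ub <- vapply(doc$reactions, num_or, 0, field = "upper_bound", default = 1000)
  obj <- vapply(doc$reactions, num_or, 0, field = "objective_coefficient",
                default = 0)
  gem(S, lb, ub, obj, id = if (!is.null(doc$id)) doc$id else
    tools::file_path_sans_ext(basename(path)))
}

read_gem_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  find <- function(xpath) xml2::xml_find_all(doc, xpath)
  attr_of <- function(nodes, name) xml2::xml_attr(nodes, name)
  sp <- find(".//*[local-name()='species']")
  boundary <- tolower(attr_of(sp, "boundaryCondition")) %in% "true"
  mets <- attr_of(sp, "id")[!boundary]
  params <- find(".//*[local-name()='parameter']")
  pval <- stats::setNames(as.numeric(attr_of(params, "value")),
                          attr_of(params, "id"))
  rx_nodes <- find(".//*[local-name()='reaction']")
  rxns <- attr_of(rx_nodes, "id")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  bound_of <- function(node, which, default) {
    ref <- xml2::xml_attr(node, which)  # fbc:lowerFluxBound etc resolves ns
    if (is.na(ref) || !(ref %in% names(pval))) default else pval[[ref]]
  }
  lb <- ub <- numeric(length(rxns))
  ignored <- character(0)
  for (i in seq_along(rx_nodes)) {
    node <- rx_nodes[[i]]
    for (side in c(-1, 1)) {
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      refs <- xml2::xml_find_all(
        node, sprintf("./*[local-name()='%s']/*[local-name()='speciesReference']", tag))
      for (ref in refs) {
        met <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        if (met %in% mets) S[met, rxns[i]] <- S[met, rxns[i]] + side * st
      }
    }
    lb[i] <- bound_of(node, "lowerFluxBound", -1000)
    ub[i] <- bound_of(node, "upperFluxBound", 1000)
    kl <- xml2::xml_find_first(node, "./*[local-name()='kineticLaw']")
    if (!inherits(kl, "xml_missing")) ignored <- c(ignored, "kineticLaw")
  }
  if (length(ignored))
    warning("ignored SBML construct(s): ", paste(unique(ignored), collapse = ", "),
            call. = FALSE)
  fo <- find(".//*[local-name()='fluxObjective']")
  if (length(fo) == 0) stop("SBML model has no fbc objective", call. = FALSE)
  obj <- numeric(length(rxns))
  orx <- attr_of(fo, "reaction")
  ocf <- as.numeric(attr_of(fo, "coefficient"))
  ocf[is.na(ocf)] <- 1
  obj[match(orx, rxns)] <- ocf
  mid <- xml2::xml_attr(xml2::xml_find_first(doc, ".//*[local-name()='model']"), "id")
  gem(S, lb, ub, obj, id = if (is.na(mid))
    tools::file_path_sans_ext(basename(path)) else mid)
}

#' Locate the exchange reaction of an external metabolite
#'
#' Matches by exchange-reaction metabolite id (with or without the `_e`
#' compartment suffix) or by the `EX_<metabolite>` naming convention.
#'
#' @param model A [gem()].
#' @param metabolite Metabolite name.
#' @return Reaction id, or `NA` when unmapped.
#' @export
find_exchange <- function(model, metabolite) {
  ex <- model$exchanges
  hit <- names(ex)[ex %in% c(metabolite, paste0(metabolite, "_e"))]
  if (length(hit) == 0)
    hit <- intersect(c(paste0("EX_", metabolite), paste0("EX_", metabolite, "_e")),
                     names(ex))
  if (length(hit) == 0) NA_character_ else hit[1]
}
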