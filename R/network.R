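#' Metabolic network container
#'
#' A `metabolic_network` holds the stoichiometric description of a metabolic
#' model together with its enzyme assignments, substrate-level regulatory
#' interactions and the designated biomass reaction.  It is the common input
#' of the constraint-based analyses (`\link{compute_reference_flux}`,
#' `\link{fba_predict}`, ...) and of the elementary-step decomposition
#' (`\link{decompose_network}`).
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `cofactor` (logical), `conc_lo`, `conc_hi` (reference concentration
#'   range, mM; `NA` allowed).
#' @param reactions data.frame with columns `id`, `reversible` (logical),
#'   `exchange` (logical), `subsystem`, and two list columns:
#'   `stoichiometry` (named numeric, negative = consumed, positive =
#'   produced; forward is left to right as written) and `enzymes`
#'   (character vector of isozyme ids, `character(0)` for uncatalysed
#'   reactions; exchange reactions must be uncatalysed).
#' @param regulations data.frame with columns `regulator` (metabolite id),
#'   `target` (reaction id) and `mode`, one of `"competitive-inhibition"`,
#'   `"uncompetitive-inhibition"`, `"mixed-inhibition"`, `"activation"`.
#' @param biomass_id id of the biomass reaction, or `NA`.
#'
#' @return an object of class `metabolic_network`.
#' @export
metabolic_network <- function(metabolites, reactions,
                              regulations = empty_regulations(),
                              biomass_id = NA_character_) {
  metabolites <- as.data.frame(metabolites)
  reactions <- as.data.frame(reactions)
  regulations <- as.data.frame(regulations)
  if (is.null(metabolites$cofactor)) metabolites$cofactor <- FALSE
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$conc_lo)) metabolites$conc_lo <- NA_real_
  if (is.null(metabolites$conc_hi)) metabolites$conc_hi <- NA_real_
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  net <- structure(
    list(metabolites = metabolites, reactions = reactions,
         regulations = regulations, biomass_id = biomass_id),
    class = "metabolic_network")
  validate_network(net)
}

#' @export
empty_regulations <- function() {
  data.frame(regulator = character(), target = character(),
             mode = character(), stringsAsFactors = FALSE)
}

regulation_modes <- c("competitive-inhibition", "uncompetitive-inhibition",
                      "mixed-inhibition", "activation")

#' Validate a metabolic network
#'
#' Checks the structural invariants: unique metabolite and reaction ids,
#' stoichiometry referring only to declared metabolites, non-exchange
#' reactions having at least one reactant and one product, regulations
#' pointing at existing species and reactions, and known regulation modes.
#' Offending identifiers are named in the error message.
#'
#' @param net a `metabolic_network`.
#' @return `net`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  mids <- net$metabolites$id
  rids <- net$reactions$id
  if (anyDuplicated(mids))
    stop("duplicate metabolite id(s): ",
         paste(unique(mids[duplicated(mids)]), collapse = ", "))
  if (anyDuplicated(rids))
    stop("duplicate reaction id(s): ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  for (i in seq_len(nrow(net$reactions))) {
    st <- net$reactions$stoichiometry[[i]]
    rid <- rids[i]
    if (length(st) == 0L) stop("reaction ", rid, " has empty stoichiometry")
    bad <- setdiff(names(st), mids)
    if (length(bad))
      stop("reaction ", rid, " references unknown metabolite(s): ",
           paste(bad, collapse = ", "))
    if (any(st == 0)) stop("reaction ", rid, " has zero coefficient")
    if (!net$reactions$exchange[i]) {
      if (!any(st < 0) || !any(st > 0))
        stop("non-exchange reaction ", rid,
             " must have at least one reactant and one product")
    }
    enz <- net$reactions$enzymes[[i]]
    if (net$reactions$exchange[i] && length(enz))
      stop("exchange reaction ", rid, " must not carry enzymes")
  }
  if (nrow(net$regulations)) {
    bad <- setdiff(net$regulations$regulator, mids)
    if (length(bad))
      stop("regulation regulator(s) not in network: ",
           paste(bad, collapse = ", "))
    bad <- setdiff(net$regulations$target, rids)
    if (length(bad))
      stop("regulation target(s) not in network: ",
           paste(bad, collapse = ", "))
    bad <- setdiff(net$regulations$mode, regulation_modes)
    if (length(bad))
      stop("unknown regulation mode(s): ", paste(bad, collapse = ", "))
    catalysed <- rids[lengths(net$reactions$enzymes) > 0L]
    bad <- setdiff(net$regulations$target, catalysed)
    if (length(bad))
      stop("regulation targets uncatalysed reaction(s): ",
           paste(bad, collapse = ", "))
  }
  if (!is.na(net$biomass_id) && !(net$biomass_id %in% rids))
    stop("biomass reaction ", net$biomass_id, " not in network")
  invisible(net)
}

#' Stoichiometric matrix
#'
#' @param net a `metabolic_network`.
#' @return dense numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoich_matrix <- function(net) {
  S <- matrix(0, nrow(net$metabolites), nrow(net$reactions),
              dimnames = list(net$metabolites$id, net$reactions$id))
  for (i in seq_len(nrow(net$reactions))) {
    st <- net$reactions$stoichiometry[[i]]
    S[names(st), i] <- st
  }
  S
}

#' Default flux bounds for a network
#'
#' Irreversible reactions are bounded below at zero; all magnitudes are
#' capped at `big` (uptake basis 100 scale).  Exchange uptake limits are
#' imposed separately by the analyses.
#'
#' @param net a `metabolic_network`.
#' @param big magnitude cap, default 1000.
#' @return list with numeric vectors `lb` and `ub`, named by reaction.
#' @export
default_bounds <- function(net, big = 1000) {
  n <- nrow(net$reactions)
  lb <- ifelse(net$reactions$reversible, -big, 0)
  ub <- rep(big, n)
  names(lb) <- names(ub) <- net$reactions$id
  list(lb = lb, ub = ub)
}

#' Enzymes of a network
#'
#' @param net a `metabolic_network`.
#' @return character vector of distinct enzyme (isozyme) ids.
#' @export
network_enzymes <- function(net) {
  unique(unlist(net$reactions$enzymes))
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("metabolic_network: ", nrow(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites, ",
      nrow(x$regulations), " regulatory interactions\n", sep = "")
  cat("  biomass reaction: ", x$biomass_id, "\n", sep = "")
  invisible(x)
}
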