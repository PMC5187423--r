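#' @title Model, data-set and parameterization I/O
#' @description The tabular dialect stores a network in three UTF-8 CSV
#'   files sharing a stem: `<stem>.metabolites.csv` (id, name,
#'   compartment, cofactor, conc_lo, conc_hi), `<stem>.reactions.csv`
#'   (id, reversible, exchange, subsystem, is_biomass, stoichiometry as
#'   `"met:coeff;met:coeff"` with negative coefficients for reactants,
#'   enzymes as `"E1;E2"`) and `<stem>.regulations.csv` (regulator,
#'   target, mode).  Flux data sets are one long CSV (strain, condition,
#'   genotype, reaction, mean, sd); parameterizations are JSON.  Fluxes
#'   are stored internally on the basis "uptake = 100"; rescaling happens
#'   only at this I/O boundary.
#' @name model_io
NULL

#' Write a network in the tabular dialect
#'
#' Output is canonical (fixed column order, full-precision numbers), so
#' write -> read -> write round-trips byte-identically.
#'
#' @param net a `metabolic_network`.
#' @param stem file stem; three CSV files are created.
#' @return `stem`, invisibly.
#' @export
write_network <- function(net, stem) {
  validate_network(net)
  met <- net$metabolites[, c("id", "name", "compartment", "cofactor",
                             "conc_lo", "conc_hi")]
  rx <- data.frame(
    id = net$reactions$id,
    reversible = net$reactions$reversible,
    exchange = net$reactions$exchange,
    subsystem = net$reactions$subsystem,
    is_biomass = net$reactions$id == net$biomass_id &
      !is.na(net$biomass_id),
    stoichiometry = vapply(net$reactions$stoichiometry, fmt_stoich, ""),
    enzymes = vapply(net$reactions$enzymes, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  for (d in list(met, rx, net$regulations))
    check_dialect_chars(d)
  utils::write.csv(met, paste0(stem, ".metabolites.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(rx, paste0(stem, ".reactions.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(net$regulations, paste0(stem, ".regulations.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(stem)
}

fmt_stoich <- function(st) {
  paste0(names(st), ":", vapply(unname(st), format, "", digits = 15),
         collapse = ";")
}

check_dialect_chars <- function(d) {
  chr <- vapply(d, is.character, logical(1))
  for (cn in names(d)[chr])
    if (any(grepl("[,\"]", d[[cn]])))
      stop("tabular dialect forbids commas/quotes in field ", cn)
  invisible(d)
}

#' Read a network
#'
#' @param path file stem of the tabular dialect, or an SBML file.
#' @param format `"tabular"` or `"sbml"`; guessed from the path when
#'   missing (`.xml`/`.sbml` extension means SBML).
#' @param enzyme_csv,regulation_csv optional sidecar CSVs supplying
#'   enzyme assignments (`reaction,enzymes`) and regulations for SBML
#'   input, which carries stoichiometry only.
#' @return a validated `\link{metabolic_network}`.
#' @export
read_network <- function(path, format = NULL, enzyme_csv = NULL,
                         regulation_csv = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.(xml|sbml)$", path)) "sbml" else "tabular"
  if (format == "sbml")
    return(read_network_sbml(path, enzyme_csv, regulation_csv))
  met <- utils::read.csv(paste0(path, ".metabolites.csv"),
                         stringsAsFactors = FALSE)
  rx <- utils::read.csv(paste0(path, ".reactions.csv"),
                        stringsAsFactors = FALSE)
  regf <- paste0(path, ".regulations.csv")
  regs <- if (file.exists(regf))
    utils::read.csv(regf, stringsAsFactors = FALSE,
                    colClasses = "character")
  else empty_regulations()
  if (!nrow(regs)) regs <- empty_regulations()
  reactions <- data.frame(id = rx$id, reversible = rx$reversible,
                          exchange = rx$exchange,
                          subsystem = ifelse(is.na(rx$subsystem), "",
                                             rx$subsystem),
                          stringsAsFactors = FALSE)
  reactions$stoichiometry <- lapply(rx$stoichiometry, parse_stoich)
  reactions$enzymes <- lapply(rx$enzymes, function(s) {
    if (is.na(s) || s == "") character() else strsplit(s, ";")[[1]]
  })
  biomass <- rx$id[rx$is_biomass]
  metabolic_network(met, reactions, regs,
                    biomass_id = if (length(biomass)) biomass[1]
                                 else NA_character_)
}

parse_stoich <- function(s) {
  parts <- strsplit(s, ";")[[1]]
  kv <- strsplit(parts, ":")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed stoichiometry term: ",
                     paste(parts[bad], collapse = ", "))
  stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                  vapply(kv, `[`, "", 1L))
}

# SBML Level 3 core, stoichiometry only
read_network_sbml <- function(path, enzyme_csv = NULL,
                              regulation_csv = NULL) {
  doc <- xml2::read_xml(path)
  ns <- c(s = xml2::xml_ns(doc)[[1]])
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  met <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  rxn_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction",
                                  ns)
  side <- function(node, what) {
    refs <- xml2::xml_find_all(
      node, paste0("./s:", what, "/s:speciesReference"), ns)
    if (!length(refs)) return(stats::setNames(numeric(0), character(0)))
    coef <- xml2::xml_attr(refs, "stoichiometry")
    coef[is.na(coef)] <- "1"
    stats::setNames(as.numeric(coef), xml2::xml_attr(refs, "species"))
  }
  ids <- xml2::xml_attr(rxn_nodes, "id")
  reactions <- data.frame(
    id = ids,
    reversible = xml2::xml_attr(rxn_nodes, "reversible") == "true",
    exchange = FALSE, subsystem = "", stringsAsFactors = FALSE)
  reactions$stoichiometry <- lapply(rxn_nodes, function(nd) {
    r <- side(nd, "listOfReactants"); p <- side(nd, "listOfProducts")
    c(stats::setNames(-unname(r), names(r)), p)
  })
  reactions$exchange <- vapply(reactions$stoichiometry, function(st)
    all(st < 0) || all(st > 0), logical(1))
  reactions$enzymes <- rep(list(character()), nrow(reactions))
  if (!is.null(enzyme_csv)) {
    ez <- utils::read.csv(enzyme_csv, stringsAsFactors = FALSE)
    m <- match(reactions$id, ez$reaction)
    reactions$enzymes <- lapply(seq_along(m), function(i) {
      if (is.na(m[i]) || ez$enzymes[m[i]] == "") character()
      else strsplit(ez$enzymes[m[i]], ";")[[1]]
    })
  }
  regs <- if (!is.null(regulation_csv))
    utils::read.csv(regulation_csv, stringsAsFactors = FALSE)
  else empty_regulations()
  biomass <- grep("biomass", ids, ignore.case = TRUE, value = TRUE)
  metabolic_network(met, reactions, regs,
                    biomass_id = if (length(biomass)) biomass[1]
                                 else NA_character_)
}

#' Read mutant flux data sets
#'
#' Long CSV with columns `strain`, `condition`, `genotype`, `reaction`,
#' `mean` and optionally `sd`.  Genotypes use a mini-syntax:
#' `"ko:E4"`, `"iso:E3a"`, `"level:E5=2.5"`, joined with `";"`; the
#' wild-type has an empty genotype.  Each strain's fluxes are rescaled
#' so its uptake reaction equals the basis (default 100); mutant rows
#' without `sd` inherit the wild-type CV of the same reaction, following
#' the rule that wild-type confidence intervals are reused for mutants.
#'
#' @param path CSV path.
#' @param uptake_reaction uptake reaction id, default `"EX_glc"`.
#' @param basis uptake basis, default 100.
#' @return named list of `flux_dataset` objects (one per strain).
#' @export
read_flux_datasets <- function(path, uptake_reaction = "EX_glc",
                               basis = 100) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(d$sd)) d$sd <- NA_real_
  if (is.null(d$condition)) d$condition <- "aerobic_glucose"
  if (is.null(d$genotype)) d$genotype <- ""
  d$genotype[is.na(d$genotype)] <- ""
  wt_strains <- unique(d$strain[d$genotype == ""])
  wt_cv <- NULL
  if (length(wt_strains)) {
    wt <- d[d$strain == wt_strains[1], ]
    wt_cv <- stats::setNames(wt$sd / abs(wt$mean), wt$reaction)
  }
  out <- lapply(split(d, d$strain), function(ds) {
    up <- ds$mean[ds$reaction == uptake_reaction]
    scale <- if (length(up) && up[1] != 0) basis / up[1] else 1
    mean_s <- ds$mean * scale
    sd_s <- ds$sd * scale
    cv <- ifelse(!is.na(sd_s), sd_s / abs(mean_s),
                 unname(wt_cv[ds$reaction]))
    if (anyNA(cv))
      stop("no wild-type CV available for reaction(s) ",
           paste(ds$reaction[is.na(cv)], collapse = ", "),
           " in strain ", ds$strain[1])
    if (any(cv <= 0))
      stop("nonpositive CV for reaction(s) ",
           paste(ds$reaction[cv <= 0], collapse = ", "),
           " in strain ", ds$strain[1])
    structure(list(
      strain = ds$strain[1], genotype = parse_genotype(ds$genotype[1]),
      condition = ds$condition[1],
      measurements = data.frame(reaction = ds$reaction, mean = mean_s,
                                sd = ifelse(is.na(sd_s),
                                            cv * abs(mean_s), sd_s),
                                cv = cv, stringsAsFactors = FALSE),
      uptake = list(reaction = uptake_reaction, value = basis,
                    basis = basis),
      lethal = FALSE), class = "flux_dataset")
  })
  out[unique(d$strain)]
}

parse_genotype <- function(s) {
  if (is.na(s) || s == "") return(genotype())
  parts <- strsplit(s, ";")[[1]]
  ko <- sub("^ko:", "", grep("^ko:", parts, value = TRUE))
  iso <- sub("^iso:", "", grep("^iso:", parts, value = TRUE))
  lev <- grep("^level:", parts, value = TRUE)
  levels <- list()
  for (p in lev) {
    kv <- strsplit(sub("^level:", "", p), "=")[[1]]
    levels[[kv[1]]] <- as.numeric(kv[2])
  }
  bad <- parts[!grepl("^(ko|iso|level):", parts)]
  if (length(bad)) stop("malformed genotype term(s): ",
                        paste(bad, collapse = ", "))
  genotype(ko = ko, iso_ko = iso, levels = levels)
}

format_genotype <- function(gt) {
  paste(c(if (length(gt$ko)) paste0("ko:", gt$ko),
          if (length(gt$iso_ko)) paste0("iso:", gt$iso_ko),
          if (length(gt$levels)) paste0("level:", names(gt$levels), "=",
                                        unlist(gt$levels))),
        collapse = ";")
}

#' Write flux data sets to the long CSV dialect
#'
#' @param datasets named list of `flux_dataset` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_flux_datasets <- function(datasets, path) {
  rows <- lapply(datasets, function(ds) {
    data.frame(strain = ds$strain, condition = ds$condition,
               genotype = format_genotype(ds$genotype),
               reaction = ds$measurements$reaction,
               mean = ds$measurements$mean, sd = ds$measurements$sd,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

PARAM_SCHEMA_VERSION <- 1L

#' Write a parameterization (or ensemble) to JSON
#'
#' Lossless (full-precision) serialization of reversibilities, fractions,
#' anchored constants, shares and enzyme levels.
#'
#' @param param a `parameterization` or a list of them (an ensemble; an
#'   empty list writes an empty ensemble).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_parameterization <- function(param, path) {
  single <- inherits(param, "parameterization")
  plist <- if (single) list(param) else param
  body <- lapply(plist, function(p) {
    list(schema_version = PARAM_SCHEMA_VERSION,
         steps = p$steps, fractions = lapply(p$fractions, as.list),
         pool_ref = as.list(p$pool_ref),
         pool_reaction = as.list(p$pool_reaction),
         e_level = as.list(p$e_level),
         iso_tau = if (is.null(p$iso_tau)) NULL else as.list(p$iso_tau),
         reference_flux = as.list(p$reference_flux),
         basis = p$basis, seed = p$seed)
  })
  jsonlite::write_json(if (single) body[[1]] else body, path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a parameterization (or ensemble) from JSON
#'
#' @param path JSON written by `\link{write_parameterization}`.
#' @return a `parameterization`, or a list of them when the file holds an
#'   ensemble (possibly empty).
#' @export
read_parameterization <- function(path) {
  j <- jsonlite::read_json(path)
  if (!is.null(j$schema_version)) return(param_from_json(j))
  lapply(j, param_from_json)
}

param_from_json <- function(j) {
  if (is.null(j$schema_version) ||
      j$schema_version != PARAM_SCHEMA_VERSION)
    stop("parameterization schema version mismatch: expected ",
         PARAM_SCHEMA_VERSION, ", got ", j$schema_version)
  num <- function(x) stats::setNames(vapply(x, as.numeric, 0), names(x))
  scol <- function(nm) vapply(j$steps, function(r) as.character(r[[nm]]), "")
  ncol_ <- function(nm) vapply(j$steps, function(r) as.numeric(r[[nm]]), 0)
  p <- structure(list(
    steps = data.frame(
      id = scol("id"), reaction = scol("reaction"),
      R = ncol_("R"), equil_scale = ncol_("equil_scale"),
      kf = ncol_("kf"), kb = ncol_("kb"),
      stringsAsFactors = FALSE, row.names = NULL),
    fractions = lapply(j$fractions, num),
    pool_ref = num(j$pool_ref),
    pool_reaction = stats::setNames(
      vapply(j$pool_reaction, as.character, ""), names(j$pool_reaction)),
    e_level = num(j$e_level),
    reference_flux = num(j$reference_flux),
    basis = j$basis, seed = j$seed), class = "parameterization")
  if (!is.null(j$iso_tau)) p$iso_tau <- num(j$iso_tau)
  bad <- vapply(p$fractions, function(f)
    abs(sum(f) - 1) > 1e-9 || any(f < 0) || any(f > 1), logical(1))
  if (any(bad))
    stop("enzyme fractions of pool(s) ",
         paste(names(p$fractions)[bad], collapse = ", "),
         " violate the simplex invariant (must lie in [0,1], sum to 1)")
  if (any(p$steps$R < 0 | p$steps$R > 1 - R_CAP_DELTA))
    stop("reversibilities must lie in [0, 1)")
  p
}

#' Read strain designs from CSV
#'
#' Columns: `design_id`, `interventions` (e.g. `"ko:E4;up:E5;down:E2"`),
#' `product_metabolite`, `product_reaction`, `y_exp`, optional
#' `condition` and `substrate_reaction`.
#'
#' @param path CSV path.
#' @return list of `\link{strain_design}` objects.
#' @export
read_strain_designs <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(d$condition)) d$condition <- "aerobic_glucose"
  if (is.null(d$substrate_reaction)) d$substrate_reaction <- "EX_glc"
  lapply(seq_len(nrow(d)), function(i) {
    parts <- strsplit(d$interventions[i], ";")[[1]]
    kind <- sub(":.*$", "", parts)
    enz <- sub("^[^:]+:", "", parts)
    mode <- c(ko = "knockout", up = "upregulate",
              down = "downregulate")[kind]
    if (anyNA(mode)) stop("malformed intervention(s): ",
                          paste(parts[is.na(mode)], collapse = ", "))
    strain_design(d$design_id[i], stats::setNames(mode, enz),
                  d$product_metabolite[i], d$product_reaction[i],
                  d$y_exp[i], condition = d$condition[i],
                  substrate_reaction = d$substrate_reaction[i])
  })
}
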