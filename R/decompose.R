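#' @title Elementary-step decomposition
#' @description Every catalysed reaction is decomposed into an ordered
#'   sequential catalytic cycle of elementary mass-action steps with
#'   explicit enzyme-form species: one binding step per substrate molecule
#'   (declared stoichiometric order; a coefficient of 2 yields two
#'   sequential binding steps), one central conversion step, and one
#'   release step per product molecule (declared order, first product
#'   first).  Substrate-level regulations add elementary binding steps:
#'   dead-end inhibitor complexes for the inhibition modes, or an
#'   obligatory activator binding preceding the first substrate binding
#'   for activation.  Cofactors bind as ordinary substrates.  Uncatalysed
#'   reactions (the biomass drain) and exchange reactions are kept as
#'   single lumped mass-action steps.
#' @name decomposition
NULL

#' Decompose a whole network into elementary steps
#'
#' Isozymes receive independent enzyme pools, each with a full copy of
#' the catalytic cycle and of any regulatory steps on that reaction.
#'
#' @param net a validated `\link{metabolic_network}`.
#' @return an `elementary_network`: list with `species` (data.frame `id`,
#'   `type`, `pool`), `steps` (data.frame `id`, `reaction`, `pool`,
#'   `kind`, `regulatory`, and list columns `reactants`/`products`, each a
#'   named numeric of species counts), `pools` (data.frame `id`,
#'   `enzyme`, `reaction`, list column `forms`; one conservation equation
#'   per pool) and the originating `network`.
#' @export
decompose_network <- function(net) {
  validate_network(net)
  all_steps <- list(); all_pools <- list(); all_forms <- list()
  for (i in seq_len(nrow(net$reactions))) {
    rx <- net$reactions[i, ]
    regs <- net$regulations[net$regulations$target == rx$id, , drop = FALSE]
    d <- decompose_reaction(rx, regulations = regs)
    all_steps[[i]] <- d$steps
    all_pools[[i]] <- d$pools
    all_forms[[i]] <- d$forms
  }
  steps <- do.call(rbind, all_steps)
  pools <- do.call(rbind, all_pools)
  forms <- unname(unlist(all_forms))
  species <- data.frame(
    id = c(net$metabolites$id, forms),
    type = c(rep("metabolite", nrow(net$metabolites)),
             rep("enzyme_form", length(forms))),
    pool = NA_character_, stringsAsFactors = FALSE)
  if (length(forms))
    species$pool[species$type == "enzyme_form"] <-
      rep(pools$id, lengths(pools$forms))[match(forms,
                                                unlist(pools$forms))]
  rownames(steps) <- rownames(pools) <- rownames(species) <- NULL
  structure(list(species = species, steps = steps, pools = pools,
                 network = net),
            class = "elementary_network")
}

#' Decompose one reaction into its elementary steps
#'
#' @param reaction single row of a network's `reactions` table (or an
#'   equivalent one-row data.frame with list columns `stoichiometry` and
#'   `enzymes`).
#' @param regulations regulation rows targeting this reaction.
#' @return list with `steps`, `pools`, `forms` (see
#'   `\link{decompose_network}`).
#' @export
decompose_reaction <- function(reaction, regulations = empty_regulations()) {
  rx <- reaction
  st <- rx$stoichiometry[[1]]
  enzymes <- rx$enzymes[[1]]
  rid <- rx$id
  if (rx$exchange) {
    s <- step_row(paste0(rid, ".x"), rid, NA, "exchange", FALSE,
                  expand(st[st < 0]), expand(st[st > 0]))
    return(list(steps = s, pools = empty_pools(), forms = character()))
  }
  if (length(enzymes) == 0L) {
    s <- step_row(paste0(rid, ".l"), rid, NA, "lumped", FALSE,
                  lumped_side(st[st < 0]), lumped_side(st[st > 0]))
    return(list(steps = s, pools = empty_pools(), forms = character()))
  }
  coefs <- st[st != 0]
  if (any(abs(coefs) != round(abs(coefs))))
    stop("catalysed reaction ", rid,
         " has non-integer stoichiometry; cannot expand binding steps")
  subs <- expand_names(st[st < 0])
  prods <- expand_names(st[st > 0])
  act <- regulations$regulator[regulations$mode == "activation"]
  inh <- regulations[regulations$mode != "activation", , drop = FALSE]
  steps <- list(); pools <- list(); forms <- list()
  for (e in enzymes) {
    cyc <- catalytic_cycle(rid, e, subs, prods, activators = act)
    cyc <- add_inhibitions(cyc, inh)
    steps[[e]] <- cyc$steps
    pools[[e]] <- data.frame(id = cyc$pool, enzyme = e, reaction = rid,
                             stringsAsFactors = FALSE)
    pools[[e]]$forms <- list(cyc$forms)
    forms[[e]] <- cyc$forms
  }
  list(steps = do.call(rbind, steps), pools = do.call(rbind, pools),
       forms = unlist(forms, use.names = FALSE))
}

empty_pools <- function() {
  p <- data.frame(id = character(), enzyme = character(),
                  reaction = character(), stringsAsFactors = FALSE)
  p$forms <- list()
  p
}

# one catalytic cycle for one enzyme pool; activators are treated as an
# obligatory first substrate that is released again at the end of the
# cycle, so catalysis cannot proceed from the free enzyme
catalytic_cycle <- function(rid, enzyme, subs, prods, activators = character()) {
  pool <- paste(rid, enzyme, sep = ".")
  bind_seq <- c(activators, subs)
  rel_seq <- c(prods, activators)      # products first, activator(s) last
  free <- paste0("ef.", pool)
  # form ids track the bound ligands in order
  bound_forms <- vapply(seq_along(bind_seq), function(k)
    paste0(free, "..", paste(bind_seq[seq_len(k)], collapse = ".")),
    character(1))
  conv_forms <- vapply(seq_along(rel_seq), function(k)
    paste0(free, "..", paste(rev(rel_seq)[seq_len(k)], collapse = "."), "*"),
    character(1))
  conv_forms <- rev(conv_forms)        # full product complex first
  steps <- list(); n <- 0L
  cur <- free
  for (k in seq_along(bind_seq)) {
    n <- n + 1L
    kind <- if (length(activators) && k <= length(activators))
      "activation" else "binding"
    steps[[n]] <- step_row(paste0(pool, ".s", n), rid, pool, kind, FALSE,
                           counts(c(cur, bind_seq[k])),
                           counts(bound_forms[k]))
    cur <- bound_forms[k]
  }
  n <- n + 1L
  steps[[n]] <- step_row(paste0(pool, ".s", n), rid, pool, "conversion",
                         FALSE, counts(cur), counts(conv_forms[1]))
  cur <- conv_forms[1]
  for (k in seq_along(rel_seq)) {
    n <- n + 1L
    nxt <- if (k < length(rel_seq)) conv_forms[k + 1] else free
    steps[[n]] <- step_row(paste0(pool, ".s", n), rid, pool, "release",
                           FALSE, counts(cur), counts(c(rel_seq[k], nxt)))
    cur <- nxt
  }
  list(steps = do.call(rbind, steps), pool = pool,
       forms = c(free, bound_forms, conv_forms))
}

add_inhibitions <- function(cyc, inh) {
  if (!nrow(inh)) return(cyc)
  steps <- cyc$steps; forms <- cyc$forms; pool <- cyc$pool
  free <- forms[1]
  conv <- which(steps$kind == "conversion")
  es_form <- names(steps$reactants[[conv]])[1]   # fully substrate-bound form
  for (i in seq_len(nrow(inh))) {
    I <- inh$regulator[i]; mode <- inh$mode[i]
    if (!mode %in% regulation_modes) stop("unknown regulation mode: ", mode)
    if (mode %in% c("competitive-inhibition", "mixed-inhibition")) {
      f <- paste0(free, ".reg.", I)
      steps <- rbind(steps, step_row(paste0(pool, ".reg", nrow(steps) + 1L),
                                     steps$reaction[1], pool, "regulatory",
                                     TRUE, counts(c(free, I)), counts(f)))
      forms <- c(forms, f)
    }
    if (mode %in% c("uncompetitive-inhibition", "mixed-inhibition")) {
      f <- paste0(es_form, ".reg.", I)
      steps <- rbind(steps, step_row(paste0(pool, ".reg", nrow(steps) + 1L),
                                     steps$reaction[1], pool, "regulatory",
                                     TRUE, counts(c(es_form, I)), counts(f)))
      forms <- c(forms, f)
    }
  }
  list(steps = steps, pool = pool, forms = forms)
}

#' Attach one regulatory interaction to an elementary network
#'
#' Inhibition modes add dead-end inhibitor-binding steps (on the free
#' enzyme, on the fully substrate-bound complex, or both for mixed
#' inhibition) to every pool of the target reaction.  Activation rebuilds
#' the target reaction's cycles with an obligatory activator binding
#' before the first substrate binding.
#'
#' @param en an `elementary_network`.
#' @param regulation one-row data.frame (`regulator`, `target`, `mode`).
#' @return the modified `elementary_network`.
#' @export
attach_regulation <- function(en, regulation) {
  stopifnot(inherits(en, "elementary_network"))
  net <- en$network
  if (!regulation$mode %in% regulation_modes)
    stop("unknown regulation mode: ", regulation$mode)
  net$regulations <- rbind(net$regulations,
                           regulation[, c("regulator", "target", "mode")])
  validate_network(net)
  decompose_network(net)
}

step_row <- function(id, reaction, pool, kind, regulatory, reac, prod) {
  s <- data.frame(id = id, reaction = reaction, pool = pool, kind = kind,
                  regulatory = regulatory, stringsAsFactors = FALSE)
  s$reactants <- list(reac)
  s$products <- list(prod)
  s
}

# named numeric of counts from a character vector with repetition
counts <- function(x) {
  t <- table(x)
  stats::setNames(as.numeric(t), names(t))
}

# expand a (negative or positive) stoichiometry chunk into repeated names
expand_names <- function(st) {
  if (!length(st)) return(character())
  rep(names(st), times = abs(st))
}

expand <- function(st) {
  if (!length(st)) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(abs(as.numeric(st)), names(st))
}

# lumped mass action keeps fractional exponents (biomass coefficients)
lumped_side <- function(st) expand(st)

#' Elementary stoichiometric matrix
#'
#' @param en an `elementary_network`.
#' @return dense matrix species x steps; column sums over each enzyme
#'   pool's forms are zero (structural pool conservation).
#' @export
elementary_stoich_matrix <- function(en) {
  N <- matrix(0, nrow(en$species), nrow(en$steps),
              dimnames = list(en$species$id, en$steps$id))
  for (s in seq_len(nrow(en$steps))) {
    r <- en$steps$reactants[[s]]; p <- en$steps$products[[s]]
    if (length(r)) N[names(r), s] <- N[names(r), s] - r
    if (length(p)) N[names(p), s] <- N[names(p), s] + p
  }
  N
}

#' Net stoichiometry recovered from a reaction's catalytic cycle
#'
#' Sums the metabolite rows of one pool's non-regulatory steps; at unit
#' flux through the cycle this must reproduce the original reaction
#' stoichiometry.
#'
#' @param en an `elementary_network`.
#' @param pool_id pool to sum.
#' @return named numeric over metabolites (zeros dropped).
#' @export
cycle_net_stoichiometry <- function(en, pool_id) {
  sel <- en$steps$pool %in% pool_id & !en$steps$regulatory
  N <- elementary_stoich_matrix(en)
  mets <- en$species$id[en$species$type == "metabolite"]
  v <- rowSums(N[mets, sel, drop = FALSE])
  v[abs(v) > 1e-12]
}

#' @export
print.elementary_network <- function(x, ...) {
  cat("elementary_network: ", nrow(x$steps), " steps, ",
      nrow(x$pools), " enzyme pools, ", nrow(x$species), " species\n",
      sep = "")
  invisible(x)
}
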