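#' Rule-based MT1-MMP / TIMP-2 / proMMP-2 reaction network
#'
#' The membrane protease MT1-MMP (M14), its endogenous inhibitor TIMP-2 (T2)
#' and the soluble gelatinase proMMP-2 (M2) assemble combinatorially on the
#' invadopodial membrane: M14 homodimerizes, T2 occupies an M14 catalytic
#' site, proMMP-2 docks onto a bound T2, and the resulting quadruple complex
#' (M14.M14.T2.M2) releases active MMP-2 by the action of the T2-free M14.
#' T2-free M14 and active MMP-2 both bind and cleave an immobile
#' fibronectin-like ECM substrate (fn). Membrane complexes live in two surface
#' pools: pool D (constant insertion, density-dependent internalization) and
#' pool X (docking-site-limited insertion, constant internalization). All
#' membrane species internalize, carrying bound partners with them; species
#' engaged with the immobile ECM do not.
#'
#' Rather than a hand-typed reaction list, the network is generated from these
#' binding rules, with a monomer-conservation self-check on every reaction.
#' A membrane complex is represented by the multiset of its M14 catalytic-site
#' states (`free`, `T2`, `T2M2`, `fn`), so canonical names are
#' order-invariant.
#'
#' @name reaction-network
NULL

.site_states <- c("free", "T2", "T2M2", "fn")

#' Binding rules for network generation
#'
#' @param dimerization,t2_binding,m2_binding,fn_binding Logical switches for
#'   the four binding rules. Disabling `dimerization` (or `t2_binding` or
#'   `m2_binding`) removes the quadruple complex and hence all proMMP-2
#'   activation.
#' @export
network_rules <- function(dimerization = TRUE, t2_binding = TRUE,
                          m2_binding = TRUE, fn_binding = TRUE) {
  structure(list(dimerization = dimerization, t2_binding = t2_binding,
                 m2_binding = m2_binding, fn_binding = fn_binding),
            class = "network_rules")
}

site_unit <- function(state, pool) {
  switch(state,
         free = paste0("M14_", pool),
         T2   = paste0("M14_", pool, ".T2"),
         T2M2 = paste0("M14_", pool, ".T2.M2"),
         fn   = paste0("M14_", pool, ".fn"))
}

mem_id <- function(pool, cf, ct, cm, cn) {
  units <- c(rep(site_unit("free", pool), cf), rep(site_unit("T2", pool), ct),
             rep(site_unit("T2M2", pool), cm), rep(site_unit("fn", pool), cn))
  paste(units, collapse = ".")
}

mem_row <- function(pool, cf, ct, cm, cn, type = "membrane") {
  id <- mem_id(pool, cf, ct, cm, cn)
  data.frame(id = if (type == "internalized") paste0("int:", id) else id,
             type = type, compartment = switch(type,
               membrane = paste0("membrane_pool", pool),
               internalized = "internalized"),
             pool = pool, n_free = cf, n_t2 = ct, n_t2m2 = cm, n_fn = cn,
             m14 = cf + ct + cm + cn, t2 = ct + cm, m2 = cm, fn = cn,
             stringsAsFactors = FALSE)
}

simple_row <- function(id, compartment, m14 = 0, t2 = 0, m2 = 0, fn = 0) {
  data.frame(id = id, type = switch(compartment,
               extracellular = "soluble", ecm = "ecm", reservoir = "reservoir",
               internalized = "internalized"),
             compartment = compartment, pool = NA_character_,
             n_free = 0, n_t2 = 0, n_t2m2 = 0, n_fn = 0,
             m14 = m14, t2 = t2, m2 = m2, fn = fn, stringsAsFactors = FALSE)
}

#' Enumerate all reachable molecular species
#'
#' Generates every membrane complex reachable under the binding rules up to
#' `max_m14` MT1-MMP monomers per complex, in both surface pools, plus the
#' soluble, ECM, vesicular-reservoir and internalized species.
#'
#' @param max_m14 Maximum number of M14 monomers per complex (>= 2; proMMP-2
#'   activation requires the dimer).
#' @param rules A [network_rules()].
#' @param pools Character vector of surface pools.
#' @return A data frame of species with composition counts and compartments.
#' @export
enumerate_species <- function(max_m14 = 2L, rules = network_rules(),
                              pools = c("X", "D")) {
  if (max_m14 < 2L) stop("max_m14 must be >= 2 (activation requires the dimer)")
  allowed <- c(TRUE, rules$t2_binding, rules$t2_binding && rules$m2_binding,
               rules$fn_binding)
  n_max <- if (rules$dimerization) max_m14 else 1L
  rows <- list()
  for (pool in pools) {
    for (n in seq_len(n_max)) {
      combos <- expand.grid(cf = 0:n, ct = 0:n, cm = 0:n, cn = 0:n)
      combos <- combos[rowSums(combos) == n, , drop = FALSE]
      keep <- (allowed[2] | combos$ct == 0) & (allowed[3] | combos$cm == 0) &
        (allowed[4] | combos$cn == 0)
      combos <- combos[keep, , drop = FALSE]
      for (i in seq_len(nrow(combos)))
        rows[[length(rows) + 1L]] <-
          mem_row(pool, combos$cf[i], combos$ct[i], combos$cm[i], combos$cn[i])
    }
  }
  mem <- do.call(rbind, rows)
  ints <- mem[mem$n_fn == 0, , drop = FALSE]
  ints$id <- paste0("int:", ints$id)
  ints$type <- "internalized"
  ints$compartment <- "internalized"

  activation_on <- rules$dimerization && rules$t2_binding && rules$m2_binding
  sol <- list(
    simple_row("T2", "extracellular", t2 = 1),
    simple_row("M2pro", "extracellular", m2 = 1),
    simple_row("fn", "ecm", fn = 1),
    simple_row("M14_ves", "reservoir", m14 = 1)
  )
  if (activation_on) {
    sol <- c(sol, list(simple_row("M2act", "extracellular", m2 = 1)))
    if (rules$t2_binding)
      sol <- c(sol, list(simple_row("M2act.T2", "extracellular", t2 = 1, m2 = 1)))
    if (rules$fn_binding)
      sol <- c(sol, list(simple_row("M2act.fn", "ecm", m2 = 1, fn = 1)))
  }
  if (rules$fn_binding)
    sol <- c(sol, list(simple_row("fn_deg", "ecm", fn = 1)))
  out <- rbind(mem, ints, do.call(rbind, sol))
  out <- out[order(out$type, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# multiset of per-monomer site states for a membrane species row
site_multiset <- function(row) {
  c(rep("free", row$n_free), rep("T2", row$n_t2),
    rep("T2M2", row$n_t2m2), rep("fn", row$n_fn))
}

counts_from_sites <- function(sites) {
  c(cf = sum(sites == "free"), ct = sum(sites == "T2"),
    cm = sum(sites == "T2M2"), cn = sum(sites == "fn"))
}

# distinct unordered splits of a site multiset into two non-empty parts,
# with the number of index-level ways each split can occur
multiset_splits <- function(sites) {
  n <- length(sites)
  if (n < 2L) return(list())
  seen <- new.env(parent = emptyenv())
  for (k in seq_len(n %/% 2)) {
    idx <- utils::combn(n, k, simplify = FALSE)
    for (sub in idx) {
      a <- sort(sites[sub]); b <- sort(sites[-sub])
      if (2L * k == n && paste(a, collapse = ",") > paste(b, collapse = ","))
        { tmp <- a; a <- b; b <- tmp }
      key <- paste(paste(a, collapse = ","), paste(b, collapse = ","), sep = "|")
      prev <- if (!is.null(seen[[key]])) seen[[key]]$ways else 0L
      seen[[key]] <- list(a = a, b = b, ways = prev + 1L)
    }
  }
  # equal-size splits are reached from both the subset and its complement;
  # halve that double count
  lapply(as.list(seen), function(s) {
    if (length(s$a) == length(s$b)) s$ways <- s$ways %/% 2L
    s
  })
}

#' Default rate constants and turnover parameters
#'
#' Binding, catalytic, insertion and internalization constants for the
#' invadopodium model, in micromolar-and-seconds units. The pool turnover
#' rates `k_D` and `k_Xint` come from the FRAP time constants (1/26.0 and
#' 1/259 per second, tagged `experiment-derived`); the remaining constants are
#' literature-anchored values refined by [calibrate_rates()] against the
#' package's headline simulation targets and are tagged `calibrated-default`,
#' so substituting an externally published table is a configuration-only
#' change.
#'
#' @return A named list of rate values with a `provenance` attribute.
#' @export
default_rate_table <- function() {
  vals <- c(
    kon_t2    = 0.40053,   # T2 association to an M14 catalytic site, 1/(uM s)
    koff_t2   = 2.1536e-4, # T2 dissociation, 1/s (tight-binding inhibitor)
    kon_m2    = 3.8191,    # proMMP-2 docking onto complex-bound T2, 1/(uM s)
    koff_m2   = 0.005,     # proMMP-2 undocking, 1/s
    k_act     = 1.1424,    # proMMP-2 processing by the T2-free M14, 1/s
    kon_m2t2  = 0.016074,  # active MMP-2 inactivation by T2, 1/(uM s)
    koff_m2t2 = 1e-4,      # 1/s (near-irreversible)
    kon_fn11  = 2.0112,    # M14-ECM association, 1/(uM s)
    koff_fn11 = 0.1,       # 1/s
    k_fn11p   = 0.13642,   # ECM cleavage by membrane M14, 1/s
    kon_fn2   = 2.0112,    # active MMP-2-ECM association, 1/(uM s)
    koff_fn2  = 0.1,       # 1/s
    k_fn2p    = 0.057984,  # ECM cleavage by active MMP-2, 1/s
    k_dim     = 2.0,       # M14 dimerization, 1/(uM s)
    k_undim   = 1.0,       # dimer dissociation, 1/s
    k_D       = 1 / 26.0,  # pool-D internalization, 1/s (FRAP fast constant)
    k_Xint    = 1 / 259,   # pool-X internalization, 1/s (FRAP slow constant)
    C_D       = 3.2067e-4, # pool-D insertion flux, uM/s
    k_Xins    = 0.10303,   # pool-X docking-site insertion rate, 1/s
    M_S       = 0.0037071  # pool-X docking-site capacity, uM
  )
  prov <- rep("calibrated-default", length(vals))
  names(prov) <- names(vals)
  prov[c("k_D", "k_Xint")] <- "experiment-derived"
  structure(as.list(vals), provenance = prov, class = "rate_table")
}

rate_value <- function(rates, name) {
  if (is.null(rates[[name]])) stop("unresolved rate constant: ", name)
  v <- rates[[name]]
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
    stop("invalid value for rate constant ", name)
  v
}

#' Generate the mass-action reaction set from the species list
#'
#' Emits reversible binding/unbinding edges for every legal pairing, proMMP-2
#' activation at the quadruple complex, active-MMP-2 inactivation by T2, the
#' two ECM degradation channels (`k_fn11p` for membrane M14, `k_fn2p` for
#' active MMP-2), and the pool-specific insertion/internalization processes
#' (constant insertion into pool D, docking-site-limited insertion into pool
#' X, first-order internalization of every non-ECM-bound membrane species).
#' Statistical multiplicity (e.g. two free catalytic sites in a dimer) is
#' recorded per reaction and folded into the effective rate. Every generated
#' reaction is self-checked for monomer conservation across the M14, T2, M2
#' and fn ledgers (degraded fn counts in the fn ledger).
#'
#' @param species Species data frame from [enumerate_species()].
#' @param rates A rate table (see [default_rate_table()]).
#' @param rules The [network_rules()] used for enumeration.
#' @param max_m14 Complex-size cap used for enumeration.
#' @return A `reaction_network` object (species, reactions, rates, rules).
#' @export
generate_reactions <- function(species, rates = default_rate_table(),
                               rules = network_rules(), max_m14 = 2L) {
  sp_ids <- species$id
  has <- function(id) id %in% sp_ids
  rx <- list()
  add <- function(id, reactants, products, rate_name, mult = 1, kind = "mass_action",
                  reversible = FALSE) {
    rx[[length(rx) + 1L]] <<- list(id = id, reactants = reactants,
                                   products = products, rate_name = rate_name,
                                   rate_value = rate_value(rates, rate_name),
                                   multiplicity = mult, kind = kind,
                                   reversible = reversible)
  }
  mem <- species[species$type == "membrane", , drop = FALSE]
  for (i in seq_len(nrow(mem))) {
    r <- mem[i, ]
    pool <- r$pool
    mid <- function(cf, ct, cm, cn) mem_id(pool, cf, ct, cm, cn)
    with(r, {
      if (rules$t2_binding && n_free >= 1) {
        pid <- mid(n_free - 1, n_t2 + 1, n_t2m2, n_fn)
        add(paste0("t2_on:", r$id), c(r$id, "T2"), pid, "kon_t2", n_free,
            reversible = TRUE)
      }
      if (n_t2 >= 1) {
        pid <- mid(n_free + 1, n_t2 - 1, n_t2m2, n_fn)
        add(paste0("t2_off:", r$id), r$id, c(pid, "T2"), "koff_t2", n_t2,
            reversible = TRUE)
      }
      if (rules$m2_binding && n_t2 >= 1) {
        pid <- mid(n_free, n_t2 - 1, n_t2m2 + 1, n_fn)
        add(paste0("m2_on:", r$id), c(r$id, "M2pro"), pid, "kon_m2", n_t2,
            reversible = TRUE)
      }
      if (n_t2m2 >= 1) {
        pid <- mid(n_free, n_t2 + 1, n_t2m2 - 1, n_fn)
        add(paste0("m2_off:", r$id), r$id, c(pid, "M2pro"), "koff_m2", n_t2m2,
            reversible = TRUE)
        if (n_free >= 1 && has("M2act"))
          add(paste0("act:", r$id), r$id,
              c(mid(n_free, n_t2 + 1, n_t2m2 - 1, n_fn), "M2act"),
              "k_act", n_t2m2)
      }
      if (rules$fn_binding && n_free >= 1) {
        pid <- mid(n_free - 1, n_t2, n_t2m2, n_fn + 1)
        add(paste0("fn_on:", r$id), c(r$id, "fn"), pid, "kon_fn11", n_free,
            reversible = TRUE)
      }
      if (n_fn >= 1) {
        pid <- mid(n_free + 1, n_t2, n_t2m2, n_fn - 1)
        add(paste0("fn_off:", r$id), r$id, c(pid, "fn"), "koff_fn11", n_fn,
            reversible = TRUE)
        add(paste0("fn_deg:", r$id), r$id, c(pid, "fn_deg"), "k_fn11p", n_fn)
      }
      # every membrane species internalizes (T2/M2 cargo goes with it);
      # ECM-engaged complexes release their immobile substrate on the way in
      int_prod <- paste0("int:", mid(n_free + n_fn, n_t2, n_t2m2, 0))
      add(paste0("int:", r$id), r$id,
          c(int_prod, rep("fn", n_fn)),
          if (pool == "D") "k_D" else "k_Xint")
    })
  }

  if (rules$dimerization) {
    for (pool in unique(mem$pool)) {
      pm <- mem[mem$pool == pool, , drop = FALSE]
      for (i in seq_len(nrow(pm))) for (j in i:nrow(pm)) {
        if (pm$m14[i] + pm$m14[j] > max_m14) next
        merged <- mem_id(pool, pm$n_free[i] + pm$n_free[j],
                         pm$n_t2[i] + pm$n_t2[j], pm$n_t2m2[i] + pm$n_t2m2[j],
                         pm$n_fn[i] + pm$n_fn[j])
        add(paste0("dim:", pm$id[i], "+", pm$id[j]),
            c(pm$id[i], pm$id[j]), merged, "k_dim", reversible = TRUE)
      }
      multi <- pm[pm$m14 >= 2, , drop = FALSE]
      for (i in seq_len(nrow(multi))) {
        sites <- site_multiset(multi[i, ])
        for (s in multiset_splits(sites)) {
          ca <- counts_from_sites(s$a); cb <- counts_from_sites(s$b)
          add(paste0("undim:", multi$id[i], ">",
                     mem_id(pool, ca[1], ca[2], ca[3], ca[4])),
              multi$id[i],
              c(mem_id(pool, ca[1], ca[2], ca[3], ca[4]),
                mem_id(pool, cb[1], cb[2], cb[3], cb[4])),
              "k_undim", s$ways, reversible = TRUE)
        }
      }
    }
  }

  if (has("M2act")) {
    if (has("M2act.T2")) {
      add("m2t2_on", c("M2act", "T2"), "M2act.T2", "kon_m2t2", reversible = TRUE)
      add("m2t2_off", "M2act.T2", c("M2act", "T2"), "koff_m2t2", reversible = TRUE)
    }
    if (has("M2act.fn")) {
      add("fn2_on", c("M2act", "fn"), "M2act.fn", "kon_fn2", reversible = TRUE)
      add("fn2_off", "M2act.fn", c("M2act", "fn"), "koff_fn2", reversible = TRUE)
      add("fn2_deg", "M2act.fn", c("M2act", "fn_deg"), "k_fn2p")
    }
  }

  # turnover: constant insertion into pool D, docking-site-limited insertion
  # into pool X, both drawing on the vesicular reservoir
  if (has("M14_D"))
    add("ins_D", "M14_ves", "M14_D", "C_D", kind = "zero_order")
  if (has("M14_X"))
    add("ins_X", "M14_ves", "M14_X", "k_Xins", kind = "saturable")

  reactions <- do.call(rbind, lapply(rx, function(r)
    data.frame(id = r$id, reactants = paste(r$reactants, collapse = " + "),
               products = paste(r$products, collapse = " + "),
               rate_name = r$rate_name, rate_value = r$rate_value,
               multiplicity = r$multiplicity, kind = r$kind,
               reversible = r$reversible, stringsAsFactors = FALSE)))
  reactions <- reactions[order(reactions$id), , drop = FALSE]
  rownames(reactions) <- NULL

  net <- structure(list(species = species, reactions = reactions,
                        rates = rates, rules = rules, max_m14 = max_m14),
                   class = "reaction_network")
  check_mass_balance(net)
  net
}

#' Build the full network in one call
#'
#' @inheritParams enumerate_species
#' @inheritParams generate_reactions
#' @export
build_network <- function(max_m14 = 2L, rates = default_rate_table(),
                          rules = network_rules()) {
  sp <- enumerate_species(max_m14, rules)
  generate_reactions(sp, rates, rules, max_m14)
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("MT1-MMP/TIMP-2/proMMP-2 reaction network\n")
  cat("  species:  ", nrow(x$species), " (", sum(x$species$type == "membrane"),
      " membrane)\n", sep = "")
  cat("  reactions:", nrow(x$reactions), "\n")
  cat("  complex-size cap:", x$max_m14, "M14 monomers\n")
  invisible(x)
}

split_side <- function(s) {
  if (identical(s, "") || is.na(s)) character() else strsplit(s, " \\+ ")[[1]]
}

#' Monomer ledger weights for every species
#'
#' Returns the count of each monomer type (M14, T2, M2, fn; degraded fn counts
#' as fn) carried by one copy of each species; used for conservation checks.
#'
#' @param network A `reaction_network`.
#' @export
ledger_weights <- function(network) {
  sp <- network$species
  m <- cbind(M14 = sp$m14, T2 = sp$t2, M2 = sp$m2, fn = sp$fn)
  rownames(m) <- sp$id
  m
}

check_mass_balance <- function(network) {
  w <- ledger_weights(network)
  for (i in seq_len(nrow(network$reactions))) {
    r <- network$reactions[i, ]
    lhs <- split_side(r$reactants); rhs <- split_side(r$products)
    bad <- setdiff(c(lhs, rhs), rownames(w))
    if (length(bad)) stop("reaction ", r$id, " references unknown species ",
                          paste(bad, collapse = ", "))
    dl <- colSums(w[lhs, , drop = FALSE]) - colSums(w[rhs, , drop = FALSE])
    if (any(dl != 0))
      stop("reaction ", r$id, " violates monomer conservation (",
           paste(names(dl)[dl != 0], collapse = ", "), ")")
  }
  invisible(TRUE)
}

#' Species reachable from an initial species set
#'
#' Fixpoint closure over the reaction list: a reaction can fire once all of
#' its reactants are reachable, making its products reachable. Used e.g. to
#' show that without TIMP-2 no proMMP-2 activation path exists.
#'
#' @param network A `reaction_network`.
#' @param init_ids Character vector of initially present species.
#' @export
reachable_species <- function(network, init_ids) {
  reach <- intersect(init_ids, network$species$id)
  repeat {
    grew <- FALSE
    for (i in seq_len(nrow(network$reactions))) {
      r <- network$reactions[i, ]
      lhs <- split_side(r$reactants)
      if (all(lhs %in% reach)) {
        new <- setdiff(split_side(r$products), reach)
        if (length(new)) { reach <- c(reach, new); grew <- TRUE }
      }
    }
    if (!grew) break
  }
  sort(reach)
}

#' Export / import the reaction list as TSV
#'
#' A human-auditable tab-separated reaction table
#' (`reaction_id  reactants  products  rate_name  rate_value  multiplicity
#' kind  reversible`) with species/reaction counts in comment headers.
#' `import_network_tsv()` reads the table back; re-exporting an imported
#' table reproduces the file.
#'
#' @param network A `reaction_network`.
#' @param path Output path.
#' @export
export_network_tsv <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# species: ", nrow(network$species)),
               paste0("# reactions: ", nrow(network$reactions))), con)
  utils::write.table(network$reactions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname export_network_tsv
#' @export
import_network_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("id", "reactants", "products", "rate_name", "rate_value",
            "multiplicity", "kind", "reversible")
  if (!all(need %in% names(df))) stop("not a reaction TSV export")
  df
}

#' Export the network as SBML Level 3
#'
#' Minimal SBML Level 3 Version 2 core document (compartments, species,
#' reactions with rate-constant parameters) for interchange with SBML-aware
#' tools. Requires the \pkg{xml2} package.
#'
#' @param network A `reaction_network`.
#' @param path Output path.
#' @export
export_network_sbml <- function(network, path) {
  if (!requireNamespace("xml2", quietly = TRUE))
    stop("SBML export requires the 'xml2' package")
  sane <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model", id = "invadopodium_ecm_degradation")
  loc <- xml2::xml_add_child(model, "listOfCompartments")
  for (cmp in unique(network$species$compartment))
    xml2::xml_add_child(loc, "compartment", id = sane(cmp), constant = "true",
                        spatialDimensions = "3", size = "1")
  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(network$species))) {
    s <- network$species[i, ]
    xml2::xml_add_child(los, "species", id = sane(s$id), name = s$id,
                        compartment = sane(s$compartment),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }
  lop <- xml2::xml_add_child(model, "listOfParameters")
  for (nm in names(network$rates))
    xml2::xml_add_child(lop, "parameter", id = sane(nm),
                        value = format(network$rates[[nm]], digits = 15),
                        constant = "true")
  lor <- xml2::xml_add_child(model, "listOfReactions")
  for (i in seq_len(nrow(network$reactions))) {
    r <- network$reactions[i, ]
    rn <- xml2::xml_add_child(lor, "reaction", id = paste0("r", i),
                              name = r$id, reversible = "false")
    lrx <- xml2::xml_add_child(rn, "listOfReactants")
    for (sid in split_side(r$reactants))
      xml2::xml_add_child(lrx, "speciesReference", species = sane(sid),
                          stoichiometry = "1", constant = "true")
    lpx <- xml2::xml_add_child(rn, "listOfProducts")
    for (sid in split_side(r$products))
      xml2::xml_add_child(lpx, "speciesReference", species = sane(sid),
                          stoichiometry = "1", constant = "true")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
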