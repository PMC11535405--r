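## Reaction network: species inventory, reaction parsing, stoichiometry,
## atom/charge balance and mass-action rate laws for water radiolysis.

#' Built-in registry of water radiolysis species
#'
#' Species produced by water radiolysis and their elemental composition
#' (H, O), charge (elementary units) and, for reservoir species, a fixed
#' molar concentration. Reaction tables may extend or override the registry
#' with `@species` lines; tokens not declared anywhere are parse errors.
#'
#' Water is a constant-concentration species at 55.3 M. H3O+ and OH- are
#' dynamic by default (acid-base and recombination reactions consume them);
#' [pin_species()] switches them to fixed concentrations (buffered mode).
#'
#' @return data.frame with columns `name`, `charge`, `H`, `O`,
#'   `const_conc` (NA for dynamic species).
#' @examples
#' species_registry()[c("OH", "O2-"), ]
#' @export
species_registry <- function() {
  df <- data.frame(
    name = c("eaq", "OH", "H", "H2", "H2O2", "O2", "O2-", "HO2", "HO2-",
             "H3O+", "OH-", "H2O"),
    charge = c(-1L, 0L, 0L, 0L, 0L, 0L, -1L, 0L, -1L, 1L, -1L, 0L),
    H = c(0L, 1L, 1L, 2L, 2L, 0L, 0L, 1L, 1L, 3L, 1L, 2L),
    O = c(0L, 1L, 0L, 0L, 2L, 2L, 2L, 2L, 2L, 1L, 1L, 1L),
    const_conc = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA,
                   .WATER_MOLARITY),
    stringsAsFactors = FALSE
  )
  rownames(df) <- df$name
  df
}

# Alternative spellings seen in the literature, mapped to registry names.
.species_aliases <- c(
  "e-aq" = "eaq", "e-" = "eaq", "eaq-" = "eaq", "e_aq" = "eaq",
  "•OH" = "OH", "OH•" = "OH",
  "H•" = "H",
  "O2•-" = "O2-", "O2-•" = "O2-",
  "HO2•" = "HO2",
  "H+" = "H3O+"
)

.canon_species <- function(token) {
  token <- trimws(token)
  ifelse(token %in% names(.species_aliases),
         unname(.species_aliases[token]), token)
}

# Split one side of a reaction ("A + 2 B") into a vector of species tokens
# with multiplicity expanded ("A", "B", "B"). Terms are separated by a plus
# surrounded by whitespace, so trailing charge signs (H3O+) survive.
.parse_side <- function(side) {
  terms <- trimws(strsplit(side, "\\s\\+\\s")[[1]])
  terms <- terms[nzchar(terms)]
  out <- character(0)
  for (tm in terms) {
    m <- regmatches(tm, regexec("^([0-9]+)\\s+(.+)$", tm))[[1]]
    if (length(m) == 3) {
      out <- c(out, rep(.canon_species(m[3]), as.integer(m[2])))
    } else {
      out <- c(out, .canon_species(tm))
    }
  }
  out
}

#' Parse a reaction table into a reaction network
#'
#' Reads a delimiter-separated reaction table. Reaction rows have the fields
#' `label` (optional), `reactants -> products`, `k`, `unit` (`M-1s-1` or
#' `s-1`) and an optional free-text provenance note; fields are separated by
#' commas or tabs and the two reaction sides by `->`. Lines beginning with
#' `#` are comments. Lines beginning with `@species` declare or override a
#' species: `@species name charge nH nO [const_M]`; undeclared tokens fall
#' back to [species_registry()].
#'
#' The kinetic order of a reaction is set by its unit tag (`M-1s-1` =
#' bimolecular, `s-1` = unimolecular). Dynamic reactants fill the kinetic
#' slots first, then constant-concentration reactants (whose fixed molarity
#' multiplies the rate); any remaining constant reactants are spectators that
#' only enter the balance bookkeeping, so solvent water can be written
#' explicitly without distorting tabulated aqueous rate constants. At most
#' two dynamic reactants are allowed.
#'
#' @param text Character scalar (whole table) or character vector of lines.
#' @return An object of class `reaction_network`: list with `species`
#'   (data.frame as in [species_registry()]), `reactions` (data.frame with
#'   `label`, `reactants`, `products`, `k`, `unit`, `note`), and `S`, the
#'   species-by-reaction matrix of net stoichiometric coefficients
#'   (products minus reactants).
#' @seealso [read_reaction_table()], [default_network()], [validate_balance()]
#' @examples
#' net <- parse_reaction_table("1a, OH + OH -> H2O2, 5.50e9, M-1s-1")
#' net$reactions$k
#' @export
parse_reaction_table <- function(text) {
  if (length(text) == 1 && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  lines <- trimws(text)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]

  registry <- species_registry()
  declared <- registry[0, ]  # species declared in-file take precedence
  rxn_rows <- list()

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "@species")) {
      f <- strsplit(trimws(sub("^@species", "", ln)), "[,\t ]+")[[1]]
      if (length(f) < 4) {
        stop(sprintf("malformed @species line %d: '%s'", i, ln))
      }
      declared <- rbind(declared, data.frame(
        name = .canon_species(f[1]), charge = as.integer(f[2]),
        H = as.integer(f[3]), O = as.integer(f[4]),
        const_conc = if (length(f) >= 5) as.numeric(f[5]) else NA_real_,
        stringsAsFactors = FALSE
      ))
      next
    }
    f <- strsplit(ln, "[,\t]")[[1]]
    f <- trimws(f)
    arrow_at <- which(grepl("->", f, fixed = TRUE))
    if (length(arrow_at) != 1) {
      stop(sprintf("malformed reaction row %d (no '->'): '%s'", i, ln))
    }
    label <- if (arrow_at > 1) f[1] else sprintf("R%d", length(rxn_rows) + 1)
    if (length(f) < arrow_at + 2) {
      stop(sprintf("malformed reaction row %d (need k and unit): '%s'", i, ln))
    }
    k <- suppressWarnings(as.numeric(f[arrow_at + 1]))
    unit <- f[arrow_at + 2]
    note <- if (length(f) > arrow_at + 2) {
      paste(f[(arrow_at + 3):length(f)], collapse = ", ")
    } else ""
    if (is.na(k)) {
      stop(sprintf("malformed rate constant in row %d: '%s'", i, ln))
    }
    if (k <= 0) {
      stop(sprintf("non-positive rate constant (%g) in row %d ('%s')",
                   k, i, label))
    }
    if (!unit %in% c("M-1s-1", "s-1")) {
      stop(sprintf("unknown unit tag '%s' in row %d", unit, i))
    }
    sides <- strsplit(f[arrow_at], "->", fixed = TRUE)[[1]]
    if (length(sides) != 2) {
      stop(sprintf("malformed reaction row %d: '%s'", i, ln))
    }
    rxn_rows[[length(rxn_rows) + 1]] <- list(
      label = label,
      reactants = .parse_side(sides[1]),
      products = .parse_side(sides[2]),
      k = k, unit = unit, note = note
    )
  }

  # Resolve species in order of first appearance (declaration order for
  # in-file declarations, then appearance order in reactions).
  lookup <- function(name) {
    if (name %in% declared$name) declared[declared$name == name, , drop = FALSE]
    else if (name %in% registry$name) registry[name, , drop = FALSE]
    else stop(sprintf("unknown species token '%s'", name))
  }
  used <- declared$name
  for (r in rxn_rows) used <- c(used, r$reactants, r$products)
  used <- unique(used)
  species <- do.call(rbind, lapply(used, lookup))
  rownames(species) <- species$name

  n_sp <- nrow(species)
  n_rx <- length(rxn_rows)
  S <- matrix(0, nrow = max(n_sp, 0), ncol = n_rx,
              dimnames = list(species$name, vapply(rxn_rows, `[[`, "", "label")))
  reactions <- data.frame(
    label = character(n_rx), k = numeric(n_rx), unit = character(n_rx),
    note = character(n_rx), stringsAsFactors = FALSE
  )
  reactants <- vector("list", n_rx)
  products <- vector("list", n_rx)
  for (j in seq_len(n_rx)) {
    r <- rxn_rows[[j]]
    dyn <- r$reactants[is.na(species[r$reactants, "const_conc"])]
    if (length(dyn) > 2) {
      stop(sprintf("reaction '%s' has %d dynamic reactants (max 2)",
                   r$label, length(dyn)))
    }
    order_k <- if (r$unit == "M-1s-1") 2L else 1L
    if (length(r$reactants) < order_k) {
      stop(sprintf("reaction '%s': unit %s implies order %d but only %d reactants",
                   r$label, r$unit, order_k, length(r$reactants)))
    }
    for (sp in r$reactants) S[sp, j] <- S[sp, j] - 1
    for (sp in r$products) S[sp, j] <- S[sp, j] + 1
    reactions$label[j] <- r$label
    reactions$k[j] <- r$k
    reactions$unit[j] <- r$unit
    reactions$note[j] <- r$note
    reactants[[j]] <- r$reactants
    products[[j]] <- r$products
  }
  reactions$reactants <- reactants
  reactions$products <- products

  structure(
    list(species = species, reactions = reactions, S = S),
    class = "reaction_network"
  )
}

#' Read a reaction table from a file
#'
#' @param path Path to a reaction-table text file (format of
#'   [parse_reaction_table()]).
#' @return A `reaction_network`.
#' @export
read_reaction_table <- function(path) {
  parse_reaction_table(readLines(path, warn = FALSE))
}

#' The packaged default radiolysis reaction network
#'
#' Loads the reaction table shipped with the package: the six reactions
#' governing the hydroxyl/superoxide/peroxide interplay under oxygenated
#' pulsed irradiation (labels `1a`, `1b`, `2a`, `2b`, `2c`, `2d`, with their
#' published rate constants) plus a literature-standard low-LET water
#' radiolysis set (hydrated electron, H atom, H2, H2O2, O2, HO2/O2- acid-base
#' pair, water autoionization). Every row carries a provenance note.
#'
#' @return A `reaction_network`.
#' @examples
#' net <- default_network()
#' subset(net$reactions, label == "1a")$k  # 5.5e9
#' @export
default_network <- function() {
  read_reaction_table(
    system.file("extdata", "reactions_default.tsv", package = "flashchem",
                mustWork = TRUE)
  )
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species, %d reactions\n",
              nrow(x$species), nrow(x$reactions)))
  const <- x$species$name[!is.na(x$species$const_conc)]
  if (length(const)) {
    cat("  constant species:",
        paste(sprintf("%s (%g M)", const,
                      x$species$const_conc[!is.na(x$species$const_conc)]),
              collapse = ", "), "\n")
  }
  for (j in seq_len(nrow(x$reactions))) {
    cat(sprintf("  %-4s %s -> %s   k = %.3g %s\n",
                x$reactions$label[j],
                paste(x$reactions$reactants[[j]], collapse = " + "),
                paste(x$reactions$products[[j]], collapse = " + "),
                x$reactions$k[j], x$reactions$unit[j]))
  }
  invisible(x)
}

#' Pin species to fixed concentrations (buffered mode)
#'
#' Marks species as constant-concentration reservoirs: the integrator will
#' hold them at the given molarity (e.g. buffered pH keeps H3O+ and OH-
#' fixed).
#'
#' @param network A `reaction_network`.
#' @param ... Named molarities, e.g. `"H3O+" = 1e-7`.
#' @return The modified network.
#' @examples
#' net <- pin_species(default_network(), "H3O+" = 1e-7, "OH-" = 1e-7)
#' @export
pin_species <- function(network, ...) {
  vals <- list(...)
  for (nm in names(vals)) {
    nm2 <- .canon_species(nm)
    if (!nm2 %in% network$species$name) {
      stop(sprintf("unknown species '%s'", nm))
    }
    network$species[nm2, "const_conc"] <- as.numeric(vals[[nm]])
  }
  network
}

#' Atom and charge balance report for a network
#'
#' For each reaction, tabulates the change (products minus reactants) in H
#' atoms, O atoms and total charge. A reaction is balanced iff all three
#' deltas are zero; explicitly written solvent water is counted like any
#' other species.
#'
#' @param network A `reaction_network`.
#' @return data.frame with columns `label`, `dH`, `dO`, `dcharge`,
#'   `balanced`.
#' @examples
#' all(validate_balance(default_network())$balanced)
#' @export
validate_balance <- function(network) {
  sp <- network$species
  S <- network$S
  data.frame(
    label = network$reactions$label,
    dH = as.vector(t(S) %*% sp$H),
    dO = as.vector(t(S) %*% sp$O),
    dcharge = as.vector(t(S) %*% sp$charge),
    balanced = as.vector(t(S) %*% sp$H) == 0 &
               as.vector(t(S) %*% sp$O) == 0 &
               as.vector(t(S) %*% sp$charge) == 0,
    stringsAsFactors = FALSE
  )
}

# Precompute the kinetic structure: effective rate constants (tabulated k
# times the fixed molarity of any constant species occupying a kinetic slot)
# and, per reaction, up to two dynamic-species state indices (0 = slot empty
# or constant). Returned as a list used by reaction_rates() and the RHS.
.kinetics_index <- function(network) {
  sp <- network$species
  n_rx <- nrow(network$reactions)
  keff <- network$reactions$k
  i1 <- integer(n_rx)
  i2 <- integer(n_rx)
  for (j in seq_len(n_rx)) {
    rs <- network$reactions$reactants[[j]]
    is_const <- !is.na(sp[rs, "const_conc"])
    # dynamic reactants occupy kinetic slots first
    kin <- c(rs[!is_const], rs[is_const])
    order_k <- if (network$reactions$unit[j] == "M-1s-1") 2L else 1L
    kin <- kin[seq_len(order_k)]
    idx <- integer(0)
    for (s in kin) {
      if (is.na(sp[s, "const_conc"])) {
        idx <- c(idx, match(s, sp$name))
      } else {
        keff[j] <- keff[j] * sp[s, "const_conc"]
      }
    }
    i1[j] <- if (length(idx) >= 1) idx[1] else 0L
    i2[j] <- if (length(idx) >= 2) idx[2] else 0L
  }
  list(keff = keff, i1 = i1, i2 = i2)
}

#' Mass-action rates of every reaction at a given state
#'
#' Evaluates r_j = k_j [A][B] (bimolecular) or k_j [A] (unimolecular) for all
#' reactions. Identical reactants follow the radiation-chemistry tabulation
#' convention r = k[A]^2 with d[A]/dt = -2r (the factor 2 is carried by the
#' stoichiometry matrix). Constant-concentration reactants contribute their
#' fixed molarity.
#'
#' @param network A `reaction_network`.
#' @param conc Named numeric vector of concentrations (mol/L) for the
#'   dynamic species; names must cover `network$species$name` entries that
#'   are dynamic. Constant species are taken from the network and may be
#'   omitted.
#' @return Numeric vector of rates (mol/L/s), one per reaction, named by
#'   label.
#' @examples
#' net <- default_network()
#' r <- reaction_rates(net, c(OH = 1e-6))["1a"]  # 5.5e9 * (1e-6)^2
#' @export
reaction_rates <- function(network, conc) {
  state <- state_vector(network, conc)
  if (any(state < 0)) {
    stop("negative concentration in state: ",
         paste(names(state)[state < 0], collapse = ", "))
  }
  ki <- .kinetics_index(network)
  y1 <- ifelse(ki$i1 > 0, state[pmax(ki$i1, 1)], 1)
  y2 <- ifelse(ki$i2 > 0, state[pmax(ki$i2, 1)], 1)
  r <- ki$keff * y1 * y2
  names(r) <- network$reactions$label
  r
}

#' Assemble a full state vector in network species order
#'
#' Fills unspecified dynamic species with 0 and constant species with their
#' fixed molarity; named entries in `conc` override both.
#'
#' @param network A `reaction_network`.
#' @param conc Named numeric vector (possibly partial), mol/L.
#' @return Named numeric vector over all network species, in declaration
#'   order (the deterministic state layout used by the integrator).
#' @export
state_vector <- function(network, conc = numeric(0)) {
  sp <- network$species
  state <- ifelse(is.na(sp$const_conc), 0, sp$const_conc)
  names(state) <- sp$name
  if (length(conc)) {
    nms <- .canon_species(names(conc))
    bad <- setdiff(nms, sp$name)
    if (length(bad)) {
      stop("unknown species in state: ", paste(bad, collapse = ", "))
    }
    state[nms] <- as.numeric(conc)
  }
  state
}
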