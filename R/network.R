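# Small stoichiometric networks: construction from a reaction-list dialect,
# TSV round trip, and the virtual-carbon augmentation used to minimize
# casamino-acid uptake.

#' Build a metabolic network from a reaction table
#'
#' Reactions are given as equation strings in the dialect
#' `"2 A + B -> C"`; an empty side denotes an exchange with the
#' environment (`"-> A"` is a source, `"A ->"` a sink).  Stoichiometric
#' coefficients precede the metabolite name, separated by a space.
#'
#' @param reactions data frame with columns `id`, `equation`, `lb`, `ub`
#'   (flux bounds, e.g. mmol/gDW/h).
#' @param biomass id of the biomass reaction (optional).
#' @param ngam id of the non-growth-associated maintenance (NGAM) ATP-drain
#'   reaction (optional); its lower bound is its fixed value.
#' @param uptakes ids of substrate uptake reactions (sources the
#'   consistency check may close).
#' @return An object of class `"metabolic_network"`: list with the
#'   stoichiometric matrix `S` (metabolites x reactions), `mets`, `rxns`,
#'   `lb`, `ub`, `reversible` (`lb < 0`), `equations`, and the designated
#'   `biomass`, `ngam`, `uptakes`.
#' @examples
#' net <- metabolic_network(data.frame(
#'   id = c("up", "conv", "bio"),
#'   equation = c("-> A", "A -> B", "B ->"),
#'   lb = 0, ub = c(10, 1000, 1000)), biomass = "bio")
#' @export
metabolic_network <- function(reactions, biomass = NULL, ngam = NULL,
                              uptakes = character(0)) {
  need <- c("id", "equation", "lb", "ub")
  if (!all(need %in% names(reactions))) {
    stop("reactions needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(reactions$id)) {
    stop("duplicate reaction ids", call. = FALSE)
  }
  parsed <- lapply(reactions$equation, parse_reaction_equation)
  mets <- sort(unique(unlist(lapply(parsed, function(p) names(p)))))
  S <- matrix(0, length(mets), nrow(reactions),
              dimnames = list(mets, reactions$id))
  for (j in seq_along(parsed)) S[names(parsed[[j]]), j] <- parsed[[j]]
  if (any(reactions$lb > reactions$ub)) {
    stop("lower bound exceeds upper bound for: ",
         paste(reactions$id[reactions$lb > reactions$ub], collapse = ", "),
         call. = FALSE)
  }
  for (id in c(biomass, ngam, uptakes)) {
    if (!id %in% reactions$id) {
      stop("designated reaction not in network: ", id, call. = FALSE)
    }
  }
  structure(list(S = S, mets = mets, rxns = reactions$id,
                 lb = stats::setNames(as.numeric(reactions$lb), reactions$id),
                 ub = stats::setNames(as.numeric(reactions$ub), reactions$id),
                 reversible = stats::setNames(reactions$lb < 0, reactions$id),
                 equations = stats::setNames(reactions$equation,
                                             reactions$id),
                 biomass = biomass, ngam = ngam, uptakes = uptakes),
            class = "metabolic_network")
}

# "2 A + B -> C" -> named stoichiometry c(A = -2, B = -1, C = 1)
parse_reaction_equation <- function(eq) {
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) > 2 || !grepl("->", eq, fixed = TRUE)) {
    stop("malformed reaction equation: '", eq, "'", call. = FALSE)
  }
  if (length(sides) == 1) sides <- c(sides, "")
  parse_side <- function(s, sgn) {
    s <- trimws(s)
    if (s == "") return(numeric(0))
    if (grepl("^\\+|\\+$", s)) {
      stop("malformed term in equation: '", eq, "'", call. = FALSE)
    }
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      if (tm == "") stop("malformed term in equation: '", eq, "'",
                         call. = FALSE)
      parts <- strsplit(tm, "\\s+")[[1]]
      if (length(parts) == 1) {
        coef <- 1; met <- parts
      } else if (length(parts) == 2 &&
                 !is.na(suppressWarnings(as.numeric(parts[1])))) {
        coef <- as.numeric(parts[1]); met <- parts[2]
      } else {
        stop("malformed term '", tm, "' in equation", call. = FALSE)
      }
      prev <- if (met %in% names(out)) out[[met]] else 0
      out[met] <- prev + sgn * coef
    }
    out
  }
  combined <- c(parse_side(sides[1], -1), parse_side(sides[2], 1))
  if (length(combined) == 0) {
    stop("reaction equation has no metabolites: '", eq, "'", call. = FALSE)
  }
  agg <- tapply(combined, names(combined), sum)
  stats::setNames(as.numeric(agg), names(agg))
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("metabolic network: %d metabolites, %d reactions\n",
              length(x$mets), length(x$rxns)))
  if (!is.null(x$biomass)) cat("  biomass:", x$biomass, "\n")
  if (!is.null(x$ngam)) {
    cat(sprintf("  NGAM: %s (value %.4g)\n", x$ngam, x$lb[[x$ngam]]))
  }
  if (length(x$uptakes)) cat("  uptakes:", paste(x$uptakes, collapse = ", "),
                             "\n")
  invisible(x)
}

#' Set the NGAM value of a network
#'
#' Fixes the maintenance drain by setting the NGAM reaction's lower bound
#' to `value` (upper bound raised to at least `value`).
#'
#' @param network a [metabolic_network()] with a designated `ngam` reaction.
#' @param value non-negative maintenance flux.
#' @return The modified network.
#' @export
set_ngam <- function(network, value) {
  if (is.null(network$ngam)) stop("network has no NGAM reaction",
                                  call. = FALSE)
  stopifnot(value >= 0)
  network$lb[network$ngam] <- value
  network$ub[network$ngam] <- max(network$ub[network$ngam], value)
  network
}

#' Augment a network with a virtual carbon feed
#'
#' Implements casamino-acid uptake minimization: one new pseudo-metabolite
#' `"carbon"`, an exchange feeding it, and per amino acid a reaction
#' converting `n_C` carbon into one amino acid, where `n_C` is the amino
#' acid's carbon count.  Minimizing the carbon exchange flux then minimizes
#' total CAA carbon uptake.
#'
#' @param network a [metabolic_network()].
#' @param amino_acid_carbon_counts named integer vector: metabolite id ->
#'   number of carbon atoms (e.g. `c(gly = 2, ala = 3)`).
#' @param carbon_ub upper bound of the carbon exchange.
#' @return The augmented network; the exchange id is `"EX_carbon"` and the
#'   conversion reactions are `"VC_<amino acid>"`.
#' @export
add_virtual_carbon <- function(network, amino_acid_carbon_counts,
                               carbon_ub = 1000) {
  counts <- amino_acid_carbon_counts
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("amino_acid_carbon_counts must be a named vector", call. = FALSE)
  }
  if (any(counts <= 0) || any(counts != round(counts))) {
    stop("carbon counts must be positive integers", call. = FALSE)
  }
  absent <- setdiff(names(counts), network$mets)
  if (length(absent) > 0) {
    stop("amino acid(s) absent from the network: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  tab <- data.frame(id = network$rxns, equation = unname(network$equations),
                    lb = unname(network$lb), ub = unname(network$ub),
                    stringsAsFactors = FALSE)
  new <- data.frame(
    id = c("EX_carbon", paste0("VC_", names(counts))),
    equation = c("-> carbon",
                 sprintf("%d carbon -> %s", as.integer(counts),
                         names(counts))),
    lb = 0,
    ub = c(carbon_ub, rep(1000, length(counts))),
    stringsAsFactors = FALSE)
  metabolic_network(rbind(tab, new), biomass = network$biomass,
                    ngam = network$ngam,
                    uptakes = union(network$uptakes, "EX_carbon"))
}

#' Read and write the network TSV dialect
#'
#' A tab-separated reaction list with columns `id`, `equation`, `lb`, `ub`.
#' Designated reactions (biomass, NGAM, uptakes) are stored in `#`-prefixed
#' header comments so the round trip is lossless.
#'
#' @param path file path.
#' @return `read_network_tsv()` returns a [metabolic_network()];
#'   `write_network_tsv()` returns `path` invisibly.
#' @export
read_network_tsv <- function(path) {
  lines <- readLines(path)
  headers <- grep("^#", lines, value = TRUE)
  get_tag <- function(tag) {
    m <- grep(paste0("^#\\s*", tag, "="), headers, value = TRUE)
    if (length(m) == 0) return(NULL)
    val <- sub(paste0("^#\\s*", tag, "="), "", m[1])
    strsplit(trimws(val), ",")[[1]]
  }
  tab <- utils::read.delim(textConnection(grep("^#", lines, value = TRUE,
                                               invert = TRUE)),
                           stringsAsFactors = FALSE)
  metabolic_network(tab,
                    biomass = get_tag("biomass"),
                    ngam = get_tag("ngam"),
                    uptakes = if (is.null(get_tag("uptakes"))) character(0)
                              else get_tag("uptakes"))
}

#' @rdname read_network_tsv
#' @param network a [metabolic_network()].
#' @export
write_network_tsv <- function(network, path) {
  hdr <- character(0)
  if (!is.null(network$biomass)) hdr <- c(hdr, paste0("# biomass=",
                                                      network$biomass))
  if (!is.null(network$ngam)) hdr <- c(hdr, paste0("# ngam=", network$ngam))
  if (length(network$uptakes)) {
    hdr <- c(hdr, paste0("# uptakes=", paste(network$uptakes,
                                             collapse = ",")))
  }
  tab <- data.frame(id = network$rxns, equation = unname(network$equations),
                    lb = unname(network$lb), ub = unname(network$ub))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
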