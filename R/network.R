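#' Build the default eicosanoid reaction network
#'
#' Constructs the cyclooxygenase competition network for one of the two
#' supplementation variants. In the `"EPA"` variant arachidonic acid (AA) and
#' eicosapentaenoic acid (EPA) compete for the shared COX pool (`eCOX`):
#' AA -> PGH2 and EPA -> PGH3 are the two cybernetically controlled,
#' ATP-modulated conversions, and the unstable endoperoxides are processed
#' further by `ePtgds` (PGH2 -> PGD2, PGH3 -> PGD3) and `ePtges`
#' (PGH2 -> PGE2, PGH3 -> PGE3). PGD2 additionally dehydrates non-enzymatically
#' to PGJ2 and 15-deoxy-PGD2 (`dPGD2`) and is oxidized enzymatically to
#' 13,14-dihydro-15-keto-PGD2 (`dhkPGD2`). Every metabolite also degrades
#' first-order. The `"DHA"` variant keeps the AA branch and replaces the EPA
#' branch by a single controlled conversion DHA -> PD (an electrophilic
#' oxo-derivative) with no downstream reactions.
#'
#' The EPA variant has 13 ODE states (9 metabolites + 4 enzymes) and exposes
#' 41 free parameters; AA, EPA/DHA and ATP are measured inputs, not states.
#'
#' @param variant `"EPA"` or `"DHA"`.
#' @return An object of class `cyber_network`: a list with elements
#'   `variant`, `species` (data frame: `id`, `role`, `measured`, `series`),
#'   `reactions` (data frame: `substrate`, `product`, `enzyme`, `rate`,
#'   `controlled`, `atp`), `degradations` (data frame: `species`, `rate`),
#'   `enzyme_specs` (per-enzyme synthesis specification), `metabolites`,
#'   `enzymes`, `inputs`, and `state_names`.
#' @examples
#' net <- build_network("EPA")
#' length(net$state_names)   # 13
#' count_parameters(net)     # 41
#' @export
build_network <- function(variant = c("EPA", "DHA")) {
  if (!is.character(variant) || length(variant) != 1L ||
      !(variant %in% c("EPA", "DHA"))) {
    stop("unknown network variant: ", paste(variant, collapse = ", "),
         " (must be \"EPA\" or \"DHA\")")
  }

  omega3 <- if (variant == "EPA") "EPA" else "DHA"

  sp <- function(id, role, measured, series) {
    data.frame(id = id, role = role, measured = measured, series = series,
               stringsAsFactors = FALSE)
  }
  species <- rbind(
    sp("AA",  "input-substrate", TRUE,  "2-series"),
    sp(omega3, "input-substrate", TRUE, "3-series"),
    sp("ATP", "input-substrate", TRUE,  "none"),
    sp("PGH2",    "metabolite", FALSE, "2-series"),
    sp("PGD2",    "metabolite", TRUE,  "2-series"),
    sp("PGE2",    "metabolite", TRUE,  "2-series"),
    sp("PGJ2",    "metabolite", TRUE,  "2-series"),
    sp("dPGD2",   "metabolite", TRUE,  "2-series"),
    sp("dhkPGD2", "metabolite", TRUE,  "2-series")
  )
  rx <- function(substrate, product, enzyme, rate, controlled = FALSE,
                 atp = FALSE) {
    data.frame(substrate = substrate, product = product,
               enzyme = if (is.null(enzyme)) NA_character_ else enzyme,
               rate = rate, controlled = controlled, atp = atp,
               stringsAsFactors = FALSE)
  }
  reactions <- rbind(
    rx("AA", "PGH2", "eCOX", "kPGH2", controlled = TRUE, atp = TRUE),
    rx("PGH2", "PGD2", "ePtgds", "kPGD2"),
    rx("PGH2", "PGE2", "ePtges", "kPGE2"),
    rx("PGD2", "dhkPGD2", "edhkPGD2", "kdhkPGD2"),
    rx("PGD2", "PGJ2", NULL, "kPGJ2"),
    rx("PGD2", "dPGD2", NULL, "kdPGD2")
  )

  if (variant == "EPA") {
    species <- rbind(species,
      sp("PGH3", "metabolite", FALSE, "3-series"),
      sp("PGD3", "metabolite", TRUE,  "3-series"),
      sp("PGE3", "metabolite", TRUE,  "3-series"))
    reactions <- rbind(reactions,
      rx("EPA", "PGH3", "eCOX", "kPGH3", controlled = TRUE, atp = TRUE),
      rx("PGH3", "PGD3", "ePtgds", "kPGD3"),
      rx("PGH3", "PGE3", "ePtges", "kPGE3"))
    cox_terms <- list(
      list(driver = "AA",  k = "kePGH2", Km = "KmAA",  u = "PGH2"),
      list(driver = "EPA", k = "kePGH3", Km = "KmEPA", u = "PGH3"))
    ds_driver <- c("PGH2", "PGH3")
  } else {
    species <- rbind(species,
      sp("PD", "metabolite", FALSE, "3-series"))
    reactions <- rbind(reactions,
      rx("DHA", "PD", "eCOX", "kPD", controlled = TRUE, atp = TRUE))
    cox_terms <- list(
      list(driver = "AA",  k = "kePGH2", Km = "KmAA",  u = "PGH2"),
      list(driver = "DHA", k = "kePD",   Km = "KmDHA", u = "PD"))
    ds_driver <- "PGH2"
  }
  species <- rbind(species,
    sp("eCOX",     "enzyme", FALSE, "none"),
    sp("ePtgds",   "enzyme", FALSE, "none"),
    sp("ePtges",   "enzyme", FALSE, "none"),
    sp("edhkPGD2", "enzyme", FALSE, "none"))

  metabolites <- species$id[species$role == "metabolite"]
  degradations <- data.frame(species = metabolites,
                             rate = paste0("g", metabolites),
                             stringsAsFactors = FALSE)

  # Enzyme synthesis: constitutive alpha + Michaelis-Menten induction by the
  # substrate(s) the enzyme acts on - beta * e. Only the eCOX induction terms
  # carry the cybernetic synthesis variable u. edhkPGD2 has no constitutive
  # term (purely substrate-induced).
  enzyme_specs <- list(
    eCOX = list(enzyme = "eCOX", alpha = "aCOX", beta = "bCOX",
                terms = cox_terms, u_controlled = TRUE),
    ePtgds = list(enzyme = "ePtgds", alpha = "aPtgds", beta = "bPtgds",
                  terms = list(list(driver = ds_driver, k = "kePtgds",
                                    Km = "KmPtgds")),
                  u_controlled = FALSE),
    ePtges = list(enzyme = "ePtges", alpha = "aPtges", beta = "bPtges",
                  terms = list(list(driver = ds_driver, k = "kePtges",
                                    Km = "KmPtges")),
                  u_controlled = FALSE),
    edhkPGD2 = list(enzyme = "edhkPGD2", alpha = NULL, beta = "bdhk",
                    terms = list(list(driver = "PGD2", k = "kedhk",
                                      Km = "Kmdhk")),
                    u_controlled = FALSE)
  )

  net <- structure(list(
    variant = variant,
    species = species,
    reactions = reactions,
    degradations = degradations,
    enzyme_specs = enzyme_specs,
    metabolites = metabolites,
    enzymes = species$id[species$role == "enzyme"],
    inputs = species$id[species$role == "input-substrate"],
    controlled = reactions[reactions$controlled, , drop = FALSE]
  ), class = "cyber_network")
  net$state_names <- c(net$metabolites, net$enzymes)
  net
}

#' @export
print.cyber_network <- function(x, ...) {
  cat("Cybernetic eicosanoid network (", x$variant, " variant)\n", sep = "")
  cat("  states:     ", length(x$state_names), " (",
      length(x$metabolites), " metabolites + ", length(x$enzymes),
      " enzymes)\n", sep = "")
  cat("  inputs:     ", paste(x$inputs, collapse = ", "), "\n", sep = "")
  cat("  controlled: ",
      paste(paste0(x$controlled$substrate, " -> ", x$controlled$product),
            collapse = ", "), "\n", sep = "")
  cat("  parameters: ", count_parameters(x), "\n", sep = "")
  invisible(x)
}

#' Enumerate the free parameters of a network
#'
#' Builds the registry of every free parameter of the model: the reaction rate
#' constants, one first-order degradation rate per metabolite, the ATP
#' activity gain `kATP` and ATP decay rate `dATP`, the enzyme synthesis
#' constants (constitutive rate, degradation rate, and Michaelis-Menten
#' induction maximum rate and constant per induction term), and the initial
#' enzyme levels `x0*`. Default box bounds are attached per parameter:
#' `[0, 100]` for kinetic constants and `[0, 1]` for initial enzyme levels
#' (enzymes are in arbitrary units; only the products of rate constants and
#' enzyme levels are identifiable, so the enzyme scale is pinned by the X0
#' bound).
#'
#' @param network A `cyber_network`.
#' @return Data frame with columns `name`, `kind`, `lower`, `upper`.
#' @export
param_registry <- function(network) {
  stopifnot(inherits(network, "cyber_network"))
  reg <- function(name, kind) data.frame(name = name, kind = kind,
                                         stringsAsFactors = FALSE)
  out <- rbind(
    reg(network$reactions$rate, "rate"),
    reg(network$degradations$rate, "degradation"),
    reg(c("kATP", "dATP"), "atp")
  )
  for (es in network$enzyme_specs) {
    nm <- character(0)
    if (!is.null(es$alpha)) nm <- c(nm, es$alpha)
    nm <- c(nm, es$beta)
    for (tm in es$terms) nm <- c(nm, tm$k, tm$Km)
    out <- rbind(out, reg(nm, "enzyme"))
  }
  out <- rbind(out, reg(paste0("x0", names(network$enzyme_specs)), "x0"))
  if (anyDuplicated(out$name)) stop("duplicated parameter names in registry")
  out$lower <- 0
  out$upper <- ifelse(out$kind == "x0", 1, 100)
  rownames(out) <- NULL
  out
}

#' Count the free parameters of a network
#'
#' @param network A `cyber_network`.
#' @return Integer: the number of entries in [param_registry()]. The default
#'   EPA-variant network has 41.
#' @export
count_parameters <- function(network) {
  nrow(param_registry(network))
}

# Fetch one parameter by name with an informative error.
getp <- function(params, name) {
  i <- match(name, names(params))
  if (is.na(i) || is.na(params[[i]])) stop("missing parameter: ", name)
  params[[i]]
}
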