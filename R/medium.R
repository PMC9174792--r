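## Defined-medium representation and elemental C/N accounting.
##
## A medium definition bundles (1) the organic components, each with a
## molecular formula, a concentration tier ("group") and a concentration in
## micromolar; (2) a salt profile in millimolar keyed by ion/element name;
## (3) pass-through supplements (e.g. vitamin and trace-mineral solutions
## dosed as fold-concentrations); (4) a target pH range. Groups are
## concentration tiers, not strict chemical classes.

MEDIUM_GROUPS <- c("sugars", "organic_acids", "amino_acids", "other")

## Salt keys whose nitrogen counts as inorganic N in C:N bookkeeping.
NITROGEN_SALTS <- c(ammonium = 1L, nitrate = 1L, nitrite = 1L, urea = 2L)

#' Construct a medium component
#'
#' @param name component name (unique within a medium)
#' @param formula molecular formula string, parsed with [parse_formula()]
#' @param group concentration tier, one of `"sugars"`, `"organic_acids"`,
#'   `"amino_acids"`, `"other"`
#' @param conc_uM concentration in micromolar, finite and > 0
#' @param source provenance flag for the assignment (free text; the bundled
#'   medium fixture uses `"main_text"` vs `"inferred"`)
#' @return one-row data.frame
#' @export
medium_component <- function(name, formula, group, conc_uM,
                             source = NA_character_) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (!group %in% MEDIUM_GROUPS) {
    stop_data("unknown group '", group, "' for component '", name,
              "' (expected one of: ", paste(MEDIUM_GROUPS, collapse = ", "),
              ")")
  }
  if (!is.numeric(conc_uM) || length(conc_uM) != 1 || !is.finite(conc_uM) ||
      conc_uM <= 0) {
    stop_data("concentration for '", name, "' must be a finite number > 0")
  }
  parse_formula(formula)  # fail early on bad formulas
  data.frame(name = name, formula = formula, group = group,
             conc_uM = as.numeric(conc_uM), source = source,
             stringsAsFactors = FALSE)
}

#' Construct a medium definition
#'
#' @param name medium name
#' @param components data.frame with columns `name`, `formula`, `group`,
#'   `conc_uM` (and optionally `source`), e.g. rows built by
#'   [medium_component()]
#' @param salts named numeric vector of ion/element concentrations in mM,
#'   all >= 0; entries named `ammonium`, `nitrate`, `nitrite` or `urea`
#'   contribute inorganic N
#' @param supplements data.frame with columns `name`, `fold` (pass-through
#'   additions dosed as fold-concentration, e.g. vitamin solutions at 1x)
#' @param ph numeric length-2 target pH range `(low, high)`
#' @return object of class `medium_definition`
#' @export
medium_definition <- function(name, components,
                              salts = numeric(0),
                              supplements = NULL,
                              ph = c(7.0, 7.2)) {
  components <- validate_components(components)
  if (length(salts)) {
    if (is.null(names(salts)) || any(!nzchar(names(salts)))) {
      stop_data("salts must be a named numeric vector (ion -> mM)")
    }
    if (any(!is.finite(salts)) || any(salts < 0)) {
      stop_data("salt concentrations must be finite and >= 0")
    }
  }
  if (is.null(supplements)) {
    supplements <- data.frame(name = character(0), fold = numeric(0),
                              stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "fold") %in% names(supplements)))
  stopifnot(is.numeric(ph), length(ph) == 2, ph[1] <= ph[2])
  structure(
    list(name = name, components = components, salts = salts,
         supplements = supplements, ph = as.numeric(ph)),
    class = "medium_definition")
}

validate_components <- function(components) {
  req <- c("name", "formula", "group", "conc_uM")
  missing_cols <- setdiff(req, names(components))
  if (length(missing_cols)) {
    stop_data("components table lacks column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  if (!"source" %in% names(components)) components$source <- NA_character_
  components <- components[, c(req, "source")]
  dup <- components$name[duplicated(components$name)]
  if (length(dup)) {
    stop_data("duplicate component name(s): ",
              paste(unique(dup), collapse = ", "))
  }
  for (i in seq_len(nrow(components))) {
    res <- tryCatch({
      medium_component(components$name[i], components$formula[i],
                       components$group[i], components$conc_uM[i])
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) stop_data("component row ", i, ": ", res)
  }
  rownames(components) <- NULL
  components
}

#' @export
print.medium_definition <- function(x, ...) {
  cat("<medium_definition> ", x$name, "\n", sep = "")
  cat("  components: ", nrow(x$components), " in ",
      length(unique(x$components$group)), " groups\n", sep = "")
  cat("  salts: ", length(x$salts), "; supplements: ",
      nrow(x$supplements), "; pH ", x$ph[1], "-", x$ph[2], "\n", sep = "")
  invisible(x)
}

#' Mass concentration contributed by one element of one component
#'
#' For a component at concentration c micromolar whose formula carries
#' k atoms of the element, the contribution is k * A * c * 1e-3 mg/L,
#' where A is the standard atomic weight in g/mol. Returns 0 when the
#' element is absent.
#'
#' @param component a one-row data.frame (or list) with `formula` and
#'   `conc_uM`
#' @param element element symbol, e.g. `"C"` or `"N"`
#' @return mass concentration in mg/L
#' @examples
#' g <- medium_component("glucose", "C6H12O6", "sugars", 875)
#' element_mass_concentration(g, "C")  # 63.06 mg/L
#' @export
element_mass_concentration <- function(component, element) {
  k <- element_count(component$formula, element)
  if (k == 0L) return(0)
  if (!element %in% names(atomic_weights)) {
    stop_data("element '", element, "' missing from atomic-weight table")
  }
  k * atomic_weights[[element]] * component$conc_uM * 1e-3
}

#' Per-group organic C and N breakdown of a medium
#'
#' Sums organic carbon and nitrogen mass concentrations per concentration
#' tier and in total. `uM_each` reports the tier concentration when all
#' members of a group are equimolar (the tiered-formulation convention) and
#' NA otherwise. With `rounded = TRUE` the mg/L columns are rounded
#' half-away-from-zero to integers, matching how such breakdown tables are
#' printed.
#'
#' @param medium a `medium_definition`
#' @param rounded logical; round the mg/L columns to integers for display
#' @return data.frame with columns `group`, `uM_each`, `n_compounds`,
#'   `C_mg_L`, `N_mg_L`, ending in a `total` row
#' @export
stoichiometry_table <- function(medium, rounded = FALSE) {
  comps <- medium$components
  groups <- MEDIUM_GROUPS[MEDIUM_GROUPS %in% comps$group]
  rows <- lapply(groups, function(g) {
    sub <- comps[comps$group == g, , drop = FALSE]
    concs <- unique(sub$conc_uM)
    data.frame(
      group = g,
      uM_each = if (length(concs) == 1) concs else NA_real_,
      n_compounds = nrow(sub),
      C_mg_L = sum(vapply(seq_len(nrow(sub)), function(i)
        element_mass_concentration(sub[i, ], "C"), numeric(1))),
      N_mg_L = sum(vapply(seq_len(nrow(sub)), function(i)
        element_mass_concentration(sub[i, ], "N"), numeric(1))),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, list(data.frame(
    group = "total", uM_each = NA_real_, n_compounds = nrow(comps),
    C_mg_L = sum(vapply(rows, `[[`, numeric(1), "C_mg_L")),
    N_mg_L = sum(vapply(rows, `[[`, numeric(1), "N_mg_L")),
    stringsAsFactors = FALSE))))
  if (nrow(comps) == 0) {
    tab <- data.frame(group = "total", uM_each = NA_real_, n_compounds = 0L,
                      C_mg_L = 0, N_mg_L = 0, stringsAsFactors = FALSE)
  }
  if (rounded) {
    tab$C_mg_L <- round_half_up(tab$C_mg_L)
    tab$N_mg_L <- round_half_up(tab$N_mg_L)
  }
  attr(tab, "atomic_weights_version") <- atomic_weights_version
  rownames(tab) <- NULL
  tab
}

#' Carbon-to-nitrogen ratio of a medium
#'
#' Computed from the unrounded stoichiometry totals, on a molar or mass
#' basis, optionally adding inorganic N from the salt profile (ammonium,
#' nitrate, nitrite, urea) to the denominator. The organic-C numerator is
#' unaffected by salts.
#'
#' @param medium a `medium_definition`
#' @param basis `"molar"` (mol C / mol N) or `"mass"` (mg C / mg N)
#' @param include_inorganic_n add salt-derived N to the denominator
#' @return dimensionless ratio
#' @export
cn_ratio <- function(medium, basis = c("molar", "mass"),
                     include_inorganic_n = FALSE) {
  tab <- stoichiometry_table(medium)
  tot <- tab[tab$group == "total", ]
  n_salt <- if (include_inorganic_n) inorganic_n_mg_l(medium$salts) else 0
  cn_ratio_from_totals(tot$C_mg_L, tot$N_mg_L, n_salt_mg_l = n_salt,
                       basis = basis)
}

#' @rdname cn_ratio
#' @param c_mg_l total organic carbon in mg/L
#' @param n_mg_l total organic nitrogen in mg/L
#' @param n_salt_mg_l additional inorganic nitrogen in mg/L
#' @export
cn_ratio_from_totals <- function(c_mg_l, n_mg_l, n_salt_mg_l = 0,
                                 basis = c("molar", "mass")) {
  basis <- match.arg(basis)
  n_total <- n_mg_l + n_salt_mg_l
  if (n_total <= 0) {
    stop_data("total nitrogen is zero under the chosen options; ",
              "C:N ratio undefined")
  }
  if (basis == "molar") {
    (c_mg_l / atomic_weights[["C"]]) / (n_total / atomic_weights[["N"]])
  } else {
    c_mg_l / n_total
  }
}

## mg/L of N contributed by the salt profile (mM * N atoms * 14.007).
inorganic_n_mg_l <- function(salts) {
  if (!length(salts)) return(0)
  keys <- intersect(names(salts), names(NITROGEN_SALTS))
  sum(vapply(keys, function(k)
    salts[[k]] * NITROGEN_SALTS[[k]] * atomic_weights[["N"]], numeric(1)))
}

#' Solve the base tier concentration for a target carbon budget
#'
#' For components with formulas `tallies` and tier multipliers `mult`
#' (concentration of component i = base * mult_i), the total organic carbon
#' is linear in the base concentration, so the base achieving `target_c`
#' mg/L is the closed-form quotient
#' `target_c / sum(mult_i * nC_i * 12.011e-3)` micromolar.
#'
#' @param tallies list of element tallies or formula strings
#' @param mult positive tier multipliers, recycled to `length(tallies)`
#' @param target_c target total organic carbon in mg/L, > 0
#' @return base concentration in micromolar
#' @examples
#' solve_tier_scale(list("C6H12O6"), 1, 63.06)  # 875 uM
#' @export
solve_tier_scale <- function(tallies, mult, target_c) {
  stopifnot(length(tallies) >= 1, target_c > 0)
  mult <- rep_len(mult, length(tallies))
  if (any(mult <= 0)) stop_data("tier multipliers must be > 0")
  coef <- sum(vapply(seq_along(tallies), function(i)
    mult[i] * element_count(tallies[[i]], "C"), numeric(1))) *
    atomic_weights[["C"]] * 1e-3
  if (coef <= 0) {
    stop_data("no carbon in any component: target carbon unreachable")
  }
  target_c / coef
}

#' Weighing recipe for a medium
#'
#' Converts each organic component to the mass to weigh per litre
#' (`mg_per_L = conc_uM * molar_mass * 1e-3`) and appends the salt and
#' supplement entries as pass-through lines.
#'
#' @param medium a `medium_definition`
#' @return data.frame with columns `name`, `type`, `group`, `conc`,
#'   `unit`, `mg_per_L` (NA for pass-through lines)
#' @export
recipe <- function(medium) {
  comps <- medium$components
  met <- data.frame(
    name = comps$name, type = "metabolite", group = comps$group,
    conc = comps$conc_uM, unit = "uM",
    mg_per_L = vapply(seq_len(nrow(comps)), function(i)
      comps$conc_uM[i] * molar_mass(comps$formula[i]) * 1e-3, numeric(1)),
    stringsAsFactors = FALSE)
  salt <- data.frame(
    name = names(medium$salts), type = "salt", group = NA_character_,
    conc = as.numeric(medium$salts), unit = "mM", mg_per_L = NA_real_,
    stringsAsFactors = FALSE)
  supp <- data.frame(
    name = medium$supplements$name, type = "supplement",
    group = NA_character_, conc = medium$supplements$fold, unit = "fold",
    mg_per_L = NA_real_, stringsAsFactors = FALSE)
  out <- rbind(met, salt, supp)
  rownames(out) <- NULL
  out
}

#' Read / write medium definitions
#'
#' Two dialects. `"json"` is the full schema:
#' `{"name", "ph": [low, high], "components": [{"name", "formula",
#' "group", "conc_uM", "source"}], "salts": {"ion": mM},
#' "supplements": [{"name", "fold"}]}`.
#' `"tsv"` is a component-only table (tab-separated, mandatory header
#' `name formula group conc_uM [source]`); salts, supplements and pH take
#' their defaults on read. `write_medium()` followed by `read_medium()` is
#' the identity field-for-field for the fields a dialect carries.
#'
#' @param path file path
#' @param dialect `"json"` or `"tsv"` (default: from the file extension)
#' @return `read_medium()`: a `medium_definition`
#' @export
read_medium <- function(path, dialect = NULL) {
  dialect <- dialect %||% dialect_from_path(path)
  if (dialect == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    comps <- as.data.frame(raw$components, stringsAsFactors = FALSE)
    salts <- unlist(raw$salts) %||% numeric(0)
    supp <- if (!is.null(raw$supplements) && length(raw$supplements)) {
      as.data.frame(raw$supplements, stringsAsFactors = FALSE)
    } else NULL
    medium_definition(raw$name %||% "medium", comps, salts = salts,
                      supplements = supp,
                      ph = as.numeric(raw$ph %||% c(7.0, 7.2)))
  } else if (dialect == "tsv") {
    comps <- read_tsv(path)
    medium_definition(sub("\\.[^.]*$", "", basename(path)), comps)
  } else {
    stop_data("unknown medium dialect '", dialect, "'")
  }
}

#' @rdname read_medium
#' @param medium a `medium_definition`
#' @export
write_medium <- function(medium, path, dialect = NULL) {
  dialect <- dialect %||% dialect_from_path(path)
  if (dialect == "json") {
    obj <- list(
      name = medium$name, ph = medium$ph,
      components = medium$components,
      salts = as.list(medium$salts),
      supplements = medium$supplements)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else if (dialect == "tsv") {
    write_tsv(medium$components, path)
  } else {
    stop_data("unknown medium dialect '", dialect, "'")
  }
  invisible(path)
}

dialect_from_path <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("json", "tsv")) ext else
    stop_data("cannot infer medium dialect from extension '.", ext, "'")
}
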