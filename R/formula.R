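## Molecular-formula parsing and elemental bookkeeping.
##
## An "element tally" is a named integer vector (element symbol -> atom
## count), always stored in canonical Hill order: C first, H second, then
## all remaining elements alphabetically (plain alphabetical when no carbon
## is present).

#' Standard atomic weights bundled with the package
#'
#' A fixed table of standard atomic weights (IUPAC 2021 abridged values,
#' four significant decimals at most) so that every mass computed by the
#' package is deterministic and independent of any external source. The
#' table version is exposed so reports can state which weights were used.
#'
#' @format named numeric vector, element symbol -> g/mol
#' @export
atomic_weights <- c(
  H = 1.008,  He = 4.003, Li = 6.94,   Be = 9.012,  B = 10.81,
  C = 12.011, N = 14.007, O = 15.999,  F = 18.998,  Na = 22.990,
  Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Mn = 54.938, Fe = 55.845,
  Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38, Se = 78.971,
  Br = 79.904, Mo = 95.95, I = 126.904, W = 183.84
)

#' @rdname atomic_weights
#' @export
atomic_weights_version <- "IUPAC-2021-abridged"

#' Parse a molecular formula into an element tally
#'
#' Accepts conventional condensed formulas with optional parenthesised
#' groups carrying integer multipliers and hydrate suffixes written with a
#' middle dot, period or asterisk (e.g. `"MgSO4.7H2O"`,
#' `"Ca(NO3)2"`). Element symbols must appear in the bundled
#' [atomic_weights] table.
#'
#' @param text a single non-empty formula string
#' @return named integer vector of atom counts in Hill order
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("Ca(NO3)2")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) ||
      !nzchar(trimws(text))) {
    stop_data("formula must be a single non-empty string")
  }
  s <- trimws(text)
  ## split off hydrate segments: "·nH2O", ".nH2O", "*nH2O"
  parts <- strsplit(s, "[·•.*]")[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0) stop_data("malformed formula: '", text, "'")
  total <- integer(0)
  for (part in parts) {
    mult <- 1L
    m <- regmatches(part, regexec("^([0-9]+)(.*)$", part))[[1]]
    if (length(m) == 3 && nzchar(m[2])) {
      mult <- as.integer(m[2])
      part <- m[3]
      if (!nzchar(part)) stop_data("malformed count in formula: '", text, "'")
    }
    tally <- parse_segment(part, text)
    total <- tally_add(total, tally, mult)
  }
  tally_canonical(total)
}

## Recursive-descent parser for one hydrate-free segment.
parse_segment <- function(s, full) {
  chars <- strsplit(s, "")[[1]]
  pos <- 1L
  n <- length(chars)

  peek <- function() if (pos <= n) chars[pos] else ""
  take <- function() { ch <- chars[pos]; pos <<- pos + 1L; ch }

  read_int <- function(default = 1L) {
    if (!grepl("^[0-9]$", peek())) return(default)
    digs <- character(0)
    while (grepl("^[0-9]$", peek())) digs <- c(digs, take())
    val <- suppressWarnings(as.integer(paste(digs, collapse = "")))
    if (is.na(val) || val < 1L) {
      stop_data("malformed count '", paste(digs, collapse = ""),
                "' in formula: '", full, "'")
    }
    val
  }

  read_group <- function() {
    tally <- integer(0)
    repeat {
      ch <- peek()
      if (ch == "" || ch == ")") break
      if (ch == "(") {
        take()
        inner <- read_group()
        if (peek() != ")") {
          stop_data("unbalanced parentheses in formula: '", full, "'")
        }
        take()
        tally <- tally_add(tally, inner, read_int())
      } else if (grepl("^[A-Z]$", ch)) {
        sym <- take()
        if (grepl("^[a-z]$", peek())) sym <- paste0(sym, take())
        if (!sym %in% names(atomic_weights)) {
          stop_data("unknown element symbol '", sym, "' in formula: '",
                    full, "'")
        }
        cnt <- read_int()
        tally <- tally_add(tally, stats::setNames(cnt, sym), 1L)
      } else {
        stop_data("malformed token '", ch, "' in formula: '", full, "'")
      }
    }
    tally
  }

  out <- read_group()
  if (pos <= n) {
    if (peek() == ")") stop_data("unbalanced parentheses in formula: '",
                                 full, "'")
    stop_data("malformed token '", peek(), "' in formula: '", full, "'")
  }
  if (length(out) == 0) stop_data("formula contains no elements: '", full, "'")
  out
}

tally_add <- function(a, b, mult = 1L) {
  for (el in names(b)) {
    a[el] <- (if (el %in% names(a)) a[[el]] else 0L) + b[[el]] * mult
  }
  a
}

tally_canonical <- function(tally) {
  stopifnot(all(tally >= 1))
  els <- names(tally)
  if ("C" %in% els) {
    order_els <- c("C", if ("H" %in% els) "H",
                   sort(setdiff(els, c("C", "H"))))
  } else {
    order_els <- sort(els)
  }
  out <- as.integer(tally[order_els])
  names(out) <- order_els
  out
}

#' Serialize an element tally to a canonical Hill-order formula string
#'
#' Inverse of [parse_formula()] on canonical strings: counts of 1 are
#' implicit, C and H lead when carbon is present.
#'
#' @param tally named integer vector of atom counts
#' @return formula string
#' @export
format_formula <- function(tally) {
  tally <- validate_tally(tally)
  paste0(names(tally), ifelse(tally == 1L, "", tally), collapse = "")
}

validate_tally <- function(tally) {
  if (length(tally) == 0) stop_data("element tally is empty")
  if (is.null(names(tally)) || any(!nzchar(names(tally)))) {
    stop_data("element tally must be named by element symbol")
  }
  if (any(tally < 1) || any(tally != floor(tally))) {
    stop_data("element counts must be positive integers")
  }
  unknown <- setdiff(names(tally), names(atomic_weights))
  if (length(unknown)) {
    stop_data("element(s) missing from atomic-weight table: ",
              paste(unknown, collapse = ", "))
  }
  tally_canonical(tally)
}

#' Molar mass of an element tally
#'
#' @param tally named integer vector of atom counts (or a formula string,
#'   parsed on the fly)
#' @return molar mass in g/mol under the bundled [atomic_weights]
#' @examples
#' molar_mass("C6H12O6")  # 180.156
#' @export
molar_mass <- function(tally) {
  if (is.character(tally)) tally <- parse_formula(tally)
  tally <- validate_tally(tally)
  sum(atomic_weights[names(tally)] * tally)
}

## Atom count of one element in a tally/formula (0 when absent).
element_count <- function(tally, element) {
  if (is.character(tally) && length(tally) == 1 && !is.null(tally)) {
    tally <- parse_formula(tally)
  }
  if (element %in% names(tally)) as.integer(tally[[element]]) else 0L
}
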