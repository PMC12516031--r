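#' Attribute dictionary for a discrete choice experiment
#'
#' Builds the validated dictionary of insurance attributes used throughout the
#' design, simulation and estimation stages. Each attribute carries its levels,
#' its utility coding (`"linear"` for continuous attributes entered as a single
#' numeric column, `"dummy"` for categorical attributes entered as indicator
#' columns against a reference level), the hypothesized preference direction
#' used for dominance screening, and a `unit_scale` divisor applied to linear
#' levels before they enter utility.
#'
#' @param attributes A named list; each element is a list with fields
#'   `levels`, `coding` (`"linear"` or `"dummy"`), `reference_level`
#'   (`NULL` for linear attributes), `sign` (`"+"`, `"-"` or `"ref"`) and
#'   `unit_scale` (positive divisor, linear attributes only).
#' @return An object of class `attribute_dictionary`.
#' @seealso [huimin_attributes()] for the default five-attribute insurance
#'   dictionary.
#' @export
attribute_dictionary <- function(attributes) {
  stopifnot(is.list(attributes), length(attributes) > 0)
  if (is.null(names(attributes)) || any(names(attributes) == "")) {
    stop("every attribute must be named")
  }
  for (nm in names(attributes)) {
    a <- attributes[[nm]]
    if (!all(c("levels", "coding", "sign") %in% names(a))) {
      stop("attribute '", nm, "' must declare levels, coding and sign")
    }
    if (!a$coding %in% c("linear", "dummy")) {
      stop("attribute '", nm, "': coding must be 'linear' or 'dummy'")
    }
    if (length(a$levels) < 2 || anyDuplicated(a$levels)) {
      stop("attribute '", nm, "': needs >= 2 distinct levels")
    }
    if (a$coding == "linear") {
      if (!is.numeric(a$levels) || is.unsorted(a$levels, strictly = TRUE)) {
        stop("attribute '", nm, "': linear levels must be numeric and strictly increasing")
      }
      if (is.null(a$unit_scale)) a$unit_scale <- 1
      if (!is.numeric(a$unit_scale) || a$unit_scale <= 0) {
        stop("attribute '", nm, "': unit_scale must be > 0")
      }
      if (!a$sign %in% c("+", "-")) {
        stop("attribute '", nm, "': linear attributes need sign '+' or '-'")
      }
      a$reference_level <- NULL
    } else {
      if (is.null(a$reference_level) || !a$reference_level %in% a$levels) {
        stop("attribute '", nm, "': dummy attributes must name a reference level")
      }
      a$levels <- as.character(a$levels)
      a$reference_level <- as.character(a$reference_level)
      a$unit_scale <- 1
    }
    attributes[[nm]] <- a
  }
  structure(list(attributes = attributes), class = "attribute_dictionary")
}

#' Default insurance attribute dictionary
#'
#' The five attributes of a Huimin-type complementary inclusive health
#' insurance product: annual individual premium (RMB), degree of government
#' involvement in product operation/design/publicity, deductible (RMB, entered
#' in utility per 10 000 RMB), reimbursement rate (percentage points) and
#' value-added service package (a basic drug-discount package against three
#' expanded packages). Premium and deductible are hypothesized utility
#' decreasing, reimbursement increasing; the categorical attributes are coded
#' against their least generous level.
#'
#' @return An `attribute_dictionary` with level counts (3, 3, 3, 3, 4).
#' @export
huimin_attributes <- function() {
  attribute_dictionary(list(
    premium = list(
      levels = c(130, 170, 210), coding = "linear", sign = "-", unit_scale = 1
    ),
    government = list(
      levels = c("commercial", "moderate", "strong"), coding = "dummy",
      reference_level = "commercial", sign = "ref"
    ),
    deductible = list(
      levels = c(120000, 150000, 180000), coding = "linear", sign = "-",
      unit_scale = 10000
    ),
    reimbursement = list(
      levels = c(50, 65, 80), coding = "linear", sign = "+", unit_scale = 1
    ),
    services = list(
      levels = c("basic", "expanded1", "expanded2", "expanded3"),
      coding = "dummy", reference_level = "basic", sign = "ref"
    )
  ))
}

#' @export
print.attribute_dictionary <- function(x, ...) {
  cat("Attribute dictionary (", length(x$attributes), " attributes)\n", sep = "")
  for (nm in names(x$attributes)) {
    a <- x$attributes[[nm]]
    cat(sprintf("  %-14s %-6s levels: %s%s\n", nm, a$coding,
                paste(a$levels, collapse = ", "),
                if (a$coding == "dummy") paste0(" (ref: ", a$reference_level, ")")
                else paste0(" [sign ", a$sign, ", /", a$unit_scale, "]")))
  }
  invisible(x)
}

#' Names of the coded utility columns implied by an attribute dictionary
#'
#' Linear attributes contribute one column named after the attribute; dummy
#' attributes contribute one `attr_level` column per non-reference level.
#'
#' @param attrs An `attribute_dictionary`.
#' @return Character vector of coded column names.
#' @export
coded_names <- function(attrs) {
  unlist(lapply(names(attrs$attributes), function(nm) {
    a <- attrs$attributes[[nm]]
    if (a$coding == "linear") nm
    else paste0(nm, "_", setdiff(a$levels, a$reference_level))
  }), use.names = FALSE)
}

#' Code profiles into the utility design matrix
#'
#' @param profiles Data frame with one column per attribute (raw levels).
#' @param attrs An `attribute_dictionary`.
#' @return Numeric matrix with columns [coded_names()]: linear attributes
#'   divided by their `unit_scale`, dummy attributes expanded to indicators.
#' @export
code_profiles <- function(profiles, attrs) {
  cols <- lapply(names(attrs$attributes), function(nm) {
    a <- attrs$attributes[[nm]]
    v <- profiles[[nm]]
    if (is.null(v)) stop("profiles lack attribute column '", nm, "'")
    if (a$coding == "linear") {
      m <- matrix(as.numeric(v) / a$unit_scale, ncol = 1)
      colnames(m) <- nm
    } else {
      lv <- setdiff(a$levels, a$reference_level)
      m <- sapply(lv, function(l) as.numeric(as.character(v) == l))
      m <- matrix(m, ncol = length(lv))
      colnames(m) <- paste0(nm, "_", lv)
    }
    m
  })
  out <- do.call(cbind, cols)
  rownames(out) <- NULL
  out
}

#' Enumerate the full factorial of attribute profiles
#'
#' @param attrs An `attribute_dictionary`.
#' @return Data frame with one row per profile in the full factorial (one
#'   column per attribute); no duplicates.
#' @examples
#' nrow(enumerate_profiles(huimin_attributes())) # 3*3*3*3*4 = 324
#' @export
enumerate_profiles <- function(attrs) {
  grid <- expand.grid(lapply(attrs$attributes, `[[`, "levels"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(grid) <- names(attrs$attributes)
  grid
}

# Pairwise preference comparison on one attribute under hypothesized signs.
# Returns -1 (a worse than b), 0 (tied), 1 (a better), NA (incomparable).
compare_level <- function(a_level, b_level, attr, attr_name) {
  if (attr$coding == "linear") {
    d <- (as.numeric(a_level) - as.numeric(b_level)) * if (attr$sign == "+") 1 else -1
    return(sign(d))
  }
  # categorical partial orders
  if (attr_name == "government" ||
      identical(sort(attr$levels), sort(c("commercial", "moderate", "strong")))) {
    # commercial < moderate <= strong: moderate and strong tie (no strict order)
    rk <- c(commercial = 0, moderate = 1, strong = 1)
    return(sign(rk[[as.character(a_level)]] - rk[[as.character(b_level)]]))
  }
  # value-added style: reference < any non-reference; non-reference levels
  # mutually incomparable
  a_ref <- identical(as.character(a_level), attr$reference_level)
  b_ref <- identical(as.character(b_level), attr$reference_level)
  if (a_ref && b_ref) return(0)
  if (identical(as.character(a_level), as.character(b_level))) return(0)
  if (a_ref) return(-1)
  if (b_ref) return(1)
  NA_integer_
}

#' Is one insurance profile dominated by another?
#'
#' `TRUE` iff `profile_a` is weakly worse than `profile_b` on every attribute
#' under the hypothesized preference directions and strictly worse on at least
#' one. The basic service package is worse than any expanded package while
#' expanded packages are mutually incomparable; purely commercial operation is
#' worse than moderate or strong government involvement, which tie with each
#' other. Any incomparable attribute pair blocks dominance.
#'
#' @param profile_a,profile_b One-row data frames (or named lists) of raw
#'   attribute levels.
#' @param attrs An `attribute_dictionary`.
#' @return Logical flag.
#' @export
is_dominated <- function(profile_a, profile_b, attrs) {
  cmps <- vapply(names(attrs$attributes), function(nm) {
    compare_level(profile_a[[nm]], profile_b[[nm]], attrs$attributes[[nm]], nm)
  }, numeric(1))
  if (anyNA(cmps)) return(FALSE)
  all(cmps <= 0) && any(cmps < 0)
}

# Best/worst profile under the hypothesized signs. For tied categorical
# levels the "best" is the most involved / first expanded level.
best_profile <- function(attrs) {
  out <- lapply(names(attrs$attributes), function(nm) {
    a <- attrs$attributes[[nm]]
    if (a$coding == "linear") {
      if (a$sign == "+") max(a$levels) else min(a$levels)
    } else if (nm == "government") "strong" else setdiff(a$levels, a$reference_level)[1]
  })
  names(out) <- names(attrs$attributes)
  as.data.frame(out, stringsAsFactors = FALSE)
}

worst_profile <- function(attrs) {
  out <- lapply(names(attrs$attributes), function(nm) {
    a <- attrs$attributes[[nm]]
    if (a$coding == "linear") {
      if (a$sign == "+") min(a$levels) else max(a$levels)
    } else a$reference_level
  })
  names(out) <- names(attrs$attributes)
  as.data.frame(out, stringsAsFactors = FALSE)
}
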