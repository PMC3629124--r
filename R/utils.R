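# Internal helpers shared across modules.

# Run code with a temporary RNG state so simulators are reproducible from their
# own seed without clobbering the caller's random stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Case-insensitive symbol matching: returns the index of `x` in `table` after
# upper-casing both sides. Symbols are stored case-preserved everywhere; all
# cross-file matching goes through here.
match_ci <- function(x, table) match(toupper(x), toupper(table))

`%in_ci%` <- function(x, table) !is.na(match_ci(x, table))

# Report case collisions (two distinct spellings of the same symbol) so mixed
# case across curated lists is visible instead of silently merged.
case_collisions <- function(symbols) {
  symbols <- unique(symbols)
  up <- toupper(symbols)
  dup <- up[duplicated(up)]
  if (length(dup)) {
    split(symbols[up %in% dup], up[up %in% dup])
  } else {
    list()
  }
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' Create a gene set
#'
#' Lightweight container for a named collection of gene symbols, the unit
#' carried by GMT files and used for signatures, seed lists and backgrounds.
#' Member multiplicity is collapsed; order of first appearance is kept.
#'
#' @param name Set label (e.g. `"TS"`).
#' @param members Character vector of gene symbols; must be non-empty strings
#'   without tab characters.
#' @param description Free-text description (defaults to `""`).
#' @return An object of class `gene_set` with fields `name`, `description`,
#'   `members`.
#' @export
gene_set <- function(name, members, description = "") {
  assert_that(is.character(name) && length(name) == 1L && nzchar(name),
              "gene set name must be a non-empty string")
  members <- as.character(members)
  assert_that(all(nzchar(members)), "gene symbols must be non-empty strings")
  assert_that(!any(grepl("\t", members, fixed = TRUE)),
              "gene symbols must not contain tab characters")
  structure(list(name = name, description = description,
                 members = unique(members)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$members)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

# Accept either a gene_set or a bare character vector wherever a set of
# symbols is expected.
as_members <- function(x) {
  if (inherits(x, "gene_set")) x$members else as.character(x)
}
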