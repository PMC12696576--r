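#' The RCADS-47 item bank
#'
#' Loads the 47-item instrument definition: the assignment of each item to one
#' of the six internalizing subscales (MDD, GAD, OCD, PD, SAD, SP) and the
#' four ordered response levels (0 = Never, 1 = Sometimes, 2 = Often,
#' 3 = Always). The default mapping shipped with the package is the canonical
#' RCADS-47 layout (subscale sizes MDD 10, GAD 6, OCD 6, PD 9, SAD 7, SP 9);
#' any CSV defining a valid 47-item partition into the six subscales is
#' accepted, so the analysis never hinges on one particular mapping.
#'
#' @param path Optional path to a CSV with columns `item_id` (1-47) and
#'   `subscale`; defaults to the mapping shipped in `inst/extdata`.
#' @return An object of class `rcads_item_bank`: a list with `items` (a
#'   data.frame of `item_id`, `subscale`) and `levels` (`0:3`).
#' @examples
#' bank <- rcads_item_bank()
#' table(bank$items$subscale)
#' @export
rcads_item_bank <- function(path = NULL) {
  path <- path %||% system.file("extdata", "rcads_items.csv", package = "rcadscreen")
  items <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(sort(names(items)), c("item_id", "subscale"))) {
    stop("item bank file must have exactly the columns item_id, subscale")
  }
  items <- items[order(items$item_id), c("item_id", "subscale")]
  if (nrow(items) != 47L || !identical(as.integer(items$item_id), 1:47)) {
    stop("item bank must define items 1..47 exactly once each")
  }
  bad <- setdiff(unique(items$subscale), SUBSCALES)
  if (length(bad)) {
    stop("unknown subscale(s): ", paste(bad, collapse = ", "))
  }
  if (!setequal(unique(items$subscale), SUBSCALES)) {
    stop("item bank must use all six subscales: ", paste(SUBSCALES, collapse = ", "))
  }
  structure(list(items = items, levels = 0:3), class = "rcads_item_bank")
}

#' @export
print.rcads_item_bank <- function(x, ...) {
  cat("RCADS-47 item bank: 47 items, levels 0-3 (Never/Sometimes/Often/Always)\n")
  print(table(x$items$subscale))
  invisible(x)
}

# Item ids belonging to a subscale (or several).
bank_items <- function(bank, subscale) {
  bank$items$item_id[bank$items$subscale %in% subscale]
}

# Named list subscale -> item ids.
bank_blocks <- function(bank) {
  split(bank$items$item_id, bank$items$subscale)[SUBSCALES]
}
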