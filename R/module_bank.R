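# The module bank: one Navigation Module A map plus B duplicated
# Navigation Module B slots. Slot n = 0 is reserved (instruction copy and
# running-minimum TempMap); slot n = 1 runs the deterministic
# nearest-neighbour rule; slots n >= 2 run the randomized rule.

#' Create a module bank
#'
#' @param module_a The Navigation Module A `nav_map` (the scene map).
#' @param B Bank size (number of B-module slots, indices `n = 0..B-1`).
#'   At least 2: one reserved slot plus one working slot.
#' @param K TempMap slots per module. Only the reserved slot's
#'   running-minimum TempMap is functionally used by planning.
#' @return A `module_bank`.
#' @export
module_bank <- function(module_a, B = 1024L, K = 1024L) {
  stopifnot(inherits(module_a, "nav_map"))
  B <- as.integer(B)
  if (B < 2L) stop("bank needs B >= 2 (one reserved, one working slot)",
                   call. = FALSE)
  slots <- rep(list(list(map = NULL, temp = list())), B)
  structure(list(module_a = module_a, slots = slots, B = B,
                 K = as.integer(K), reserved = 0L,
                 instruction = NULL, broadcast_done = FALSE),
            class = "module_bank")
}

#' @export
print.module_bank <- function(x, ...) {
  filled <- sum(!vapply(x$slots, function(s) is.null(s$map), logical(1)))
  cat("<module_bank: B = ", x$B, " slots (n = 0 reserved), ",
      filled, " map(s) loaded",
      if (x$broadcast_done) ", broadcast done" else "", ">\n", sep = "")
  invisible(x)
}

# n is the 0-based slot index used throughout the planning conventions.
slot_map <- function(bank, n) bank$slots[[n + 1L]]$map

set_slot_map <- function(bank, n, map) {
  bank$slots[[n + 1L]]$map <- map
  bank
}

#' Tokenize an instruction sentence
#'
#' @param text Instruction sentence, e.g. `"go to all objects and go back"`.
#' @return An `instruction` with lowercase word tokens.
#' @export
instruction <- function(text) {
  tokens <- strsplit(tolower(trimws(text)), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) {
    stop("instruction has no tokens", call. = FALSE)
  }
  structure(list(tokens = tokens, source_text = text),
            class = "instruction")
}

ACTION_WORDS <- c("go", "place", "move")

# Lay tokens out one per cell in row-major order on a map of the given
# dimensions; action words additionally carry an action-word tag.
instruction_map <- function(instr, dims, map_id = 0L) {
  n <- length(instr$tokens)
  capacity <- prod(dims)
  if (n > capacity) stop("instruction longer than the map", call. = FALSE)
  map <- structure(list(dims = as.integer(dims), cells = list(),
                        map_id = as.integer(map_id)),
                   class = "nav_map")
  for (i in seq_len(n)) {
    idx <- i - 1L
    coord <- c(idx %% dims[1], (idx %/% dims[1]) %% dims[2],
               idx %/% (dims[1] * dims[2]))
    tok <- instr$tokens[i]
    tags <- if (tok %in% ACTION_WORDS) {
      list(nav_tag("action-word", tok))
    } else list()
    map$cells[[coord_key(coord)]] <- new_cell(features = tok, tags = tags)
  }
  map
}

instruction_from_map <- function(map) {
  keys <- map_scan_order(map)
  tokens <- vapply(keys, function(k) map$cells[[k]]$features[1],
                   character(1))
  structure(list(tokens = unname(tokens),
                 source_text = paste(tokens, collapse = " ")),
            class = "instruction")
}

#' Load an instruction into the bank
#'
#' Writes the token-per-cell instruction map into slots n = 0 and n = 1.
#' Slot n = 0 is reserved so that a copy of the instruction survives when
#' planning later overwrites the working slots.
#'
#' @param instr An [instruction()] (or a character string, tokenized).
#' @param bank A `module_bank`.
#' @return The updated bank.
#' @export
load_instruction <- function(instr, bank) {
  if (is.character(instr)) instr <- instruction(instr)
  stopifnot(inherits(instr, "instruction"), inherits(bank, "module_bank"))
  imap <- instruction_map(instr, bank$module_a$dims)
  bank <- set_slot_map(bank, 0L, imap)
  bank <- set_slot_map(bank, 1L, imap)
  bank$instruction <- instr
  bank
}

# Words that carry no destination information in a goto() instruction.
GOTO_STOPWORDS <- c("go", "to", "the", "a", "an", "and", "then",
                    "objects", "object", "all", "back")

#' Apply the goto() tagging primitive
#'
#' Reads the instruction from the reserved slot and tags the Module A map:
#' with the word `all`, every object cell receives an `<all>` marker; with
#' named features instead (e.g. `"go to the black sphere"`), exactly the
#' cells carrying all the named features are tagged; with the words
#' `go back`, the start cell receives the `<back>` marker. The count of
#' tagged destination cells decides what happens next: more than one
#' destination activates the planning bank, a single destination is a
#' direct move.
#'
#' @param bank A `module_bank` with an instruction loaded.
#' @return `list(bank = <updated bank>, map = <tagged Module A map>,
#'   location_count = <integer>)`.
#' @export
parse_goto <- function(bank) {
  stopifnot(inherits(bank, "module_bank"))
  imap <- slot_map(bank, 0L)
  if (is.null(imap)) stop("no instruction loaded", call. = FALSE)
  instr <- instruction_from_map(imap)
  tokens <- instr$tokens
  action <- tokens[tokens %in% ACTION_WORDS][1]
  if (is.na(action) || tokens[1] != "go") {
    stop("unsupported primitive: only the 'go' action word is implemented",
         call. = FALSE)
  }
  map <- bank$module_a
  skey <- start_key(map)
  if (is.null(skey)) stop("map has no start cell", call. = FALSE)

  if ("all" %in% tokens) {
    dest_keys <- object_keys(map)
  } else {
    wanted <- setdiff(tokens, GOTO_STOPWORDS)
    dest_keys <- if (length(wanted) == 0L) character() else {
      keys <- object_keys(map)
      keys[vapply(keys, function(k)
        all(wanted %in% map$cells[[k]]$features), logical(1))]
    }
  }
  for (k in dest_keys) map <- add_tag(map, k, nav_tag("all-marker"))
  if ("back" %in% tokens) map <- add_tag(map, skey, nav_tag("back-marker"))
  bank$module_a <- map
  list(bank = bank, map = map, location_count = length(dest_keys))
}

#' Broadcast the tagged map into the bank
#'
#' Copies the tagged Module A map into every non-reserved slot
#' (n = 1..B-1), stripping action words and leaving only the tagged cells.
#' The reserved slot n = 0 keeps its instruction copy untouched. Each slot
#' receives an independent copy.
#'
#' @param bank A `module_bank` after [parse_goto()].
#' @return The updated bank.
#' @export
broadcast <- function(bank) {
  stopifnot(inherits(bank, "module_bank"))
  payload <- copy_map(bank$module_a, strip_action_words = TRUE)
  for (n in seq.int(1L, bank$B - 1L)) {
    bank <- set_slot_map(bank, n, payload)
  }
  bank$broadcast_done <- TRUE
  bank
}
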