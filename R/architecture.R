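#' Peptide architecture descriptor
#'
#' Describes one multivalent peptide: its valency (number of binding epitopes,
#' a power of two), the epitope sequence presented at each arm, and the
#' branching linker architecture. The linker is written as a token string over
#' the two building blocks used on the synthesis scaffold: `J` (the branching
#' linker itself) and `O` (a PEG spacer unit). Each branching tier contributes
#' one `J` followed by as many `O`s as it has PEG units, so the token string
#' encodes the per-tier spacer counts `o1`, `o2`, `o3` (outer to inner tier; a
#' dimer has one tier, a tetramer two, an octamer three).
#'
#' @param id Character identifier, unique within a library.
#' @param valency Integer, one of 1, 2, 4, 8.
#' @param epitope_seq Epitope sequence over the 20 canonical amino-acid
#'   letters.
#' @param tokens Linker token string over `{J, O}`, at most 7 tokens (the
#'   one-hot encoding capacity, see [encode_linker()]).
#' @return An object of class `peptide_architecture`: a list with elements
#'   `id`, `valency`, `epitope_seq`, `epitope_length`, `tokens`, `o1`, `o2`,
#'   `o3`.
#' @seealso [generate_library()], [plant_kinetics()]
#' @export
peptide_architecture <- function(id, valency, epitope_seq, tokens) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  valency <- as.integer(valency)
  if (!valency %in% c(1L, 2L, 4L, 8L)) {
    stop_multikin("valency must be one of 1, 2, 4, 8 (got ", valency, ")")
  }
  check_epitope(epitope_seq)
  tokens <- check_tokens(tokens, id)
  tiers <- parse_linker_tiers(tokens)
  n_tiers <- as.integer(log2(max(valency, 2L)))
  if (length(tiers) > n_tiers) {
    stop_multikin("architecture '", id, "': token string '", tokens,
                  "' encodes ", length(tiers), " tiers but valency ", valency,
                  " has only ", n_tiers)
  }
  o <- c(tiers, rep(0L, 3L - length(tiers)))
  structure(list(id = id, valency = valency, epitope_seq = epitope_seq,
                 epitope_length = nchar(epitope_seq), tokens = tokens,
                 o1 = o[[1L]], o2 = o[[2L]], o3 = o[[3L]]),
            class = "peptide_architecture")
}

#' @export
print.peptide_architecture <- function(x, ...) {
  cat(sprintf("<peptide_architecture> %s: %d-mer of %s, linker '%s' (o1=%d, o2=%d, o3=%d)\n",
              x$id, x$valency, x$epitope_seq, x$tokens, x$o1, x$o2, x$o3))
  invisible(x)
}

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

LINKER_CAPACITY <- 7L

check_epitope <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  ch <- strsplit(seq, "")[[1L]]
  bad <- which(!ch %in% AA_ALPHABET)
  if (length(bad)) {
    stop_multikin("non-canonical amino acid '", ch[bad[1L]],
                  "' at position ", bad[1L], " of epitope '", seq, "'")
  }
  invisible(seq)
}

check_tokens <- function(tokens, id = "<unnamed>") {
  stopifnot(is.character(tokens), length(tokens) == 1L)
  ch <- strsplit(tokens, "")[[1L]]
  if (any(!ch %in% c("J", "O"))) {
    stop_multikin("architecture '", id, "': linker tokens must be over {J, O}, got '",
                  tokens, "'")
  }
  if (nchar(tokens) > LINKER_CAPACITY) {
    stop_multikin("architecture '", id, "': token string '", tokens, "' has ",
                  nchar(tokens), " tokens, exceeding the one-hot capacity of ",
                  LINKER_CAPACITY, class = "multikin_capacity_error")
  }
  tokens
}

# Split a token string into tiers: each tier is one J followed by its O run.
# Returns integer vector of per-tier O counts. Leading O's (no J) count as a
# bare spacer tier.
parse_linker_tiers <- function(tokens) {
  if (!nzchar(tokens)) return(integer(0))
  parts <- strsplit(tokens, "(?<=.)(?=J)", perl = TRUE)[[1L]]
  vapply(parts, function(p) sum(strsplit(p, "")[[1L]] == "O"), integer(1L),
         USE.NAMES = FALSE)
}

# Truncate a valency-agnostic grid token string to the tiers a valency has.
truncate_tokens <- function(tokens, valency) {
  tiers <- parse_linker_tiers(tokens)
  n_tiers <- as.integer(log2(max(valency, 2L)))
  if (length(tiers) <= n_tiers) return(tokens)
  paste0(vapply(tiers[seq_len(n_tiers)],
                function(o) paste0("J", strrep("O", o)), character(1L)),
         collapse = "")
}

# Synthetic parent epitope: the FSIVG core motif of the receptor-derived
# binding epitope, extended C-terminally with a plausible flanking sequence.
# Epitopes of length e are its N-terminal prefixes.
PARENT_EPITOPE <- "FSIVGSLPKE"

#' Generate a combinatorial multivalent peptide library
#'
#' Expands the full grid valency x epitope length x linker combination
#' (x replicate) into a list of [peptide_architecture] objects. The linker
#' grid is shared across valencies: each grid token string is truncated to the
#' number of branching tiers the valency supports, mirroring how the same
#' spacer plan is realised on smaller scaffolds.
#'
#' @param n_per_valency Replicates of each (valency, epitope, linker) cell.
#' @param valencies Integer vector over {2, 4, 8}.
#' @param epitope_lengths Integer vector of epitope lengths; epitopes are
#'   N-terminal prefixes of `parent_epitope`.
#' @param linker_grid Character vector of token strings over `{J, O}`.
#' @param parent_epitope Parent sequence the epitopes are cut from.
#' @param seed Unused for the deterministic grid itself; retained so callers
#'   can thread one seed through the whole simulation layer.
#' @return List of `peptide_architecture` objects with unique ids.
#' @examples
#' lib <- generate_library(n_per_valency = 1, valencies = c(2, 4, 8),
#'                         epitope_lengths = 5, linker_grid = "J")
#' length(lib)  # 3
#' @export
generate_library <- function(n_per_valency = 1L,
                             valencies = c(2L, 4L, 8L),
                             epitope_lengths = 5:8,
                             linker_grid = default_linker_grid(),
                             parent_epitope = PARENT_EPITOPE,
                             seed = NULL) {
  stopifnot(n_per_valency >= 1L)
  check_epitope(parent_epitope)
  if (any(epitope_lengths < 1L) || any(epitope_lengths > nchar(parent_epitope))) {
    stop_multikin("epitope lengths must lie in [1, ", nchar(parent_epitope), "]")
  }
  for (g in linker_grid) check_tokens(g, paste0("grid:", g))
  grid <- expand.grid(rep = seq_len(n_per_valency),
                      linker_i = seq_along(linker_grid),
                      e = as.integer(epitope_lengths),
                      valency = as.integer(valencies),
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    v <- grid$valency[i]
    tokens <- truncate_tokens(linker_grid[[grid$linker_i[i]]], v)
    # the grid index keeps ids unique even when truncation makes two linker
    # plans coincide on a low-valency scaffold (those become replicate
    # "synthesis batches" of the same peptide)
    id <- sprintf("v%d_e%d_l%02d_r%d", v, grid$e[i], grid$linker_i[i],
                  grid$rep[i])
    peptide_architecture(id = id, valency = v,
                         epitope_seq = substr(parent_epitope, 1L, grid$e[i]),
                         tokens = tokens)
  })
}

#' Default linker grid: nine valency-agnostic spacer plans
#'
#' All combinations of 0, 1 or 2 PEG units at the two outermost branching
#' tiers (inner tiers unspaced), written as three-tier token strings that
#' [generate_library()] truncates per valency.
#' @return Character vector of 9 token strings.
#' @export
default_linker_grid <- function() {
  g <- expand.grid(o1 = 0:2, o2 = 0:2, KEEP.OUT.ATTRS = FALSE)
  vapply(seq_len(nrow(g)),
         function(i) paste0("J", strrep("O", g$o1[i]), "J", strrep("O", g$o2[i]), "J"),
         character(1L))
}

#' Ground-truth binding kinetics
#'
#' @param k_on Association rate constant (1/M/s), strictly positive.
#' @param k_off Dissociation rate constant (1/s), strictly positive.
#' @return Object of class `ground_truth_kinetics` with `k_on`, `k_off` and
#'   `K_D = k_off / k_on` (molar).
#' @export
ground_truth_kinetics <- function(k_on, k_off) {
  assert_positive(k_on, "k_on")
  assert_positive(k_off, "k_off")
  structure(list(k_on = k_on, k_off = k_off, K_D = k_off / k_on),
            class = "ground_truth_kinetics")
}

#' @export
print.ground_truth_kinetics <- function(x, ...) {
  cat(sprintf("<kinetics> k_on = %.3g /M/s, k_off = %.3g /s, K_D = %.3g M\n",
              x$k_on, x$k_off, x$K_D))
  invisible(x)
}

#' Default rate-planting rule parameters
#'
#' The defaults encode the qualitative structure observed across multivalent
#' libraries of this kind: affinity gains are driven mainly by on-rate
#' effects, which span more than two orders of magnitude across valencies and
#' epitope lengths, while off-rates vary less than five-fold. On-rates grow
#' with valency (avidity), epitope length and outer-tier spacer count
#' (epitope accessibility); off-rates fall mildly with valency and epitope
#' length. Per-compound lognormal scatter models batch-to-batch variability.
#'
#' @return Named list of rule parameters consumed by [plant_kinetics()].
#' @export
default_rule_params <- function() {
  list(
    k_on_base = 1e3,          # /M/s, dimer with shortest epitope, no spacers
    k_off_base = 1e-2,        # /s, same reference compound
    k_on_valency_factor = 4,  # per valency doubling beyond 2
    k_off_valency_factor = 0.75,
    k_on_epitope_factor = 2,  # per residue beyond the 5-residue core
    k_off_epitope_factor = 0.95,
    k_on_o1_factor = 1.15,    # per PEG unit in the outermost tier
    k_on_log_sd = 0.2,        # lognormal scatter (natural-log sd)
    k_off_log_sd = 0.05,
    epitope_ref_length = 5L
  )
}

#' Plant ground-truth kinetics on an architecture
#'
#' Deterministic multiplicative rule plus per-compound lognormal scatter.
#' Under the default rule the full default library spans at least 100-fold in
#' k_on and at most 5-fold in k_off, higher valency and longer epitopes give
#' lower K_D in expectation.
#'
#' @param arch A [peptide_architecture].
#' @param rule_params See [default_rule_params()].
#' @param seed Integer seed for the scatter; `NULL` uses the current RNG.
#' @return A [ground_truth_kinetics] object.
#' @export
plant_kinetics <- function(arch, rule_params = default_rule_params(), seed = NULL) {
  stopifnot(inherits(arch, "peptide_architecture"))
  p <- utils::modifyList(default_rule_params(), rule_params)
  assert_positive(p$k_on_base, "k_on_base")
  assert_positive(p$k_off_base, "k_off_base")
  doublings <- log2(arch$valency) - 1
  extra_res <- arch$epitope_length - p$epitope_ref_length
  k_on <- p$k_on_base *
    p$k_on_valency_factor^doublings *
    p$k_on_epitope_factor^extra_res *
    p$k_on_o1_factor^arch$o1
  k_off <- p$k_off_base *
    p$k_off_valency_factor^doublings *
    p$k_off_epitope_factor^extra_res
  scatter <- with_seed(seed, stats::rnorm(2L))
  k_on <- k_on * exp(p$k_on_log_sd * scatter[[1L]])
  k_off <- k_off * exp(p$k_off_log_sd * scatter[[2L]])
  ground_truth_kinetics(k_on, k_off)
}

#' Plant kinetics across a whole library
#'
#' @param library List of [peptide_architecture] objects.
#' @inheritParams plant_kinetics
#' @return Data frame with one row per architecture: id, valency,
#'   epitope_length, tokens, o1, o2, o3, k_on, k_off, K_D (molar).
#' @export
plant_library_kinetics <- function(library, rule_params = default_rule_params(),
                                   seed = 1L) {
  rows <- lapply(seq_along(library), function(i) {
    a <- library[[i]]
    gt <- plant_kinetics(a, rule_params, seed = child_seed(seed, i))
    data.frame(id = a$id, valency = a$valency,
               epitope_length = a$epitope_length, epitope_seq = a$epitope_seq,
               tokens = a$tokens, o1 = a$o1, o2 = a$o2, o3 = a$o3,
               k_on = gt$k_on, k_off = gt$k_off, K_D = gt$K_D,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
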