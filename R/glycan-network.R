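#' @useDynLib glygolgi, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median prcomp kmeans rnorm runif rgamma rnbinom rexp
#'   p.adjust quantile var sd cor setNames pnorm acf
#' @importFrom utils combn read.csv write.csv head
NULL

GLYCAN_ENZYMES <- c("Man1", "Mgat1", "Man2", "Fut8", "Mgat2", "Mgat4",
                    "Mgat5", "GalT", "SiaT")

#' Construct a glycan composition state
#'
#' An N-glycan is represented at the resolution of a capillary-electrophoresis
#' profile: a composition vector, not a branching tree.  Arm isomers (e.g. the
#' two G1F isomers) are merged.
#'
#' @param man mannose count (3--9).
#' @param agn antenna GlcNAc count (0--4).
#' @param fuc core fucose indicator (0 or 1).
#' @param gal galactose count (0--`agn`).
#' @param sia sialic acid count (0--`gal`).
#' @param locked logical; `TRUE` while a core-fucosylation event is in
#'   progress.  The lock is a pseudo-state that decouples Fut8's slow rate
#'   from the other reactions; no ordinary rule fires on a locked glycan, and
#'   the lock resolves into `fuc = 1`.
#' @return an object of class `glycan_state` (named integer vector).
#' @export
glycan_state <- function(man, agn = 0L, fuc = 0L, gal = 0L, sia = 0L,
                         locked = FALSE) {
  s <- c(man = as.integer(man), agn = as.integer(agn), fuc = as.integer(fuc),
         gal = as.integer(gal), sia = as.integer(sia),
         locked = as.integer(locked))
  class(s) <- "glycan_state"
  validate_glycan_state(s)
  s
}

#' Validate a glycan state against the pathway invariants
#'
#' Checks residue bounds and the ordering constraints imposed by the
#' processing pathway: antennae only appear after trimming to Man5 (Mgat1),
#' second and later antennae only after Man2 trimming to Man3, galactoses cap
#' at the antenna count, sialic acids cap at the galactose count, and a locked
#' glycan cannot already carry core fucose.
#'
#' @param state a `glycan_state`.
#' @return the state, invisibly; signals a structural error otherwise.
#' @export
validate_glycan_state <- function(state) {
  s <- unclass(state)
  bad <- character(0)
  if (s[["man"]] < 3L || s[["man"]] > 9L) bad <- c(bad, "man outside [3, 9]")
  if (s[["agn"]] < 0L || s[["agn"]] > 4L) bad <- c(bad, "agn outside [0, 4]")
  if (!s[["fuc"]] %in% c(0L, 1L)) bad <- c(bad, "fuc not in {0, 1}")
  if (s[["gal"]] < 0L || s[["gal"]] > s[["agn"]])
    bad <- c(bad, "gal outside [0, agn]")
  if (s[["sia"]] < 0L || s[["sia"]] > s[["gal"]])
    bad <- c(bad, "sia outside [0, gal]")
  if (s[["agn"]] >= 1L && s[["man"]] > 5L)
    bad <- c(bad, "antennae require trimming to Man5 first")
  if (s[["agn"]] >= 2L && s[["man"]] != 3L)
    bad <- c(bad, "second antenna requires Man2 trimming to Man3")
  if (s[["locked"]] == 1L && s[["fuc"]] == 1L)
    bad <- c(bad, "locked glycan cannot already be fucosylated")
  if (length(bad))
    stop("invalid glycan state: ", paste(bad, collapse = "; "),
         call. = FALSE)
  invisible(state)
}

is_locked <- function(state) unclass(state)[["locked"]] == 1L

state_key <- function(state) paste(unclass(state), collapse = "-")

#' Canonical name of an (unlocked) glycan state
#'
#' Maps states to the nomenclature used for antibody glycans: `Man5`..`Man9`
#' for high-mannose forms, `G0-GN` for the mono-antennary Man3 intermediate,
#' and `G0/G0F/G1F/G2F` style names for complex biantennary forms (`F` = core
#' fucose, the digit = galactose count).  Tri-/tetra-antennary forms carry an
#' `A3`/`A4` prefix, sialylated forms an `-S<n>` suffix, and the hybrid
#' Man5-with-antenna intermediate is `Hyb-M5`.  The mapping is injective over
#' the reachable unlocked state set.
#'
#' @param state a valid, unlocked `glycan_state`.
#' @return a single character name.
#' @export
canonical_name <- function(state) {
  validate_glycan_state(state)
  if (is_locked(state))
    stop("locked states have no canonical name; resolve the lock first",
         call. = FALSE)
  s <- unclass(state)
  man <- s[["man"]]; agn <- s[["agn"]]; fuc <- s[["fuc"]]
  gal <- s[["gal"]]; sia <- s[["sia"]]
  if (agn == 0L) return(paste0("Man", man))
  f <- if (fuc == 1L) "F" else ""
  if (agn == 1L) {
    if (man == 3L) return(paste0("G", gal, f, "-GN"))
    return(paste0("Hyb-M", man, f))
  }
  pre <- if (agn > 2L) paste0("A", agn) else ""
  nm <- paste0(pre, "G", gal, f)
  if (sia > 0L) nm <- paste0(nm, "-S", sia)
  nm
}

# Named guard predicates; a rule references one by id so that rule sets can be
# serialized and alternative topologies configured without code changes.
.guard_registry <- new.env(parent = emptyenv())

register_guard <- function(id, fn) assign(id, fn, envir = .guard_registry)

lookup_guard <- function(id) {
  if (!exists(id, envir = .guard_registry, inherits = FALSE))
    stop("unknown guard id: ", id, call. = FALSE)
  get(id, envir = .guard_registry, inherits = FALSE)
}

local({
  register_guard("Man1",  function(s) s[["man"]] > 5L && s[["agn"]] == 0L)
  register_guard("Mgat1", function(s) s[["man"]] == 5L && s[["agn"]] == 0L)
  register_guard("Man2",  function(s) s[["man"]] == 5L && s[["agn"]] == 1L)
  # Fucosylation competes with galactosylation: once galactosylated, a glycan
  # is no longer a Fut8 substrate.
  register_guard("Fut8",  function(s) s[["agn"]] >= 1L && s[["fuc"]] == 0L &&
                                      s[["gal"]] == 0L)
  register_guard("Mgat2", function(s) s[["man"]] == 3L && s[["agn"]] == 1L)
  register_guard("Mgat4", function(s) s[["man"]] == 3L && s[["agn"]] == 2L)
  register_guard("Mgat5", function(s) s[["man"]] == 3L && s[["agn"]] == 3L)
  register_guard("GalT",  function(s) s[["agn"]] >= 2L && s[["gal"]] < s[["agn"]])
  register_guard("SiaT",  function(s) s[["sia"]] < s[["gal"]])
})

make_rule <- function(enzyme, guard_id, deltas) {
  structure(list(enzyme = enzyme, guard_id = guard_id,
                 guard = lookup_guard(guard_id),
                 deltas = deltas),
            class = "enzyme_rule")
}

apply_deltas <- function(state, deltas) {
  s <- unclass(state)
  for (f in names(deltas)) s[[f]] <- s[[f]] + as.integer(deltas[[f]])
  class(s) <- "glycan_state"
  validate_glycan_state(s)
  s
}

#' Default Golgi enzyme rule set
#'
#' The nine processing reactions of the canonical biantennary pathway:
#' mannosidase I trimming (Man9 to Man5, one mannose per firing), Mgat1
#' commitment of Man5, mannosidase II trimming (the two sequential trims
#' collapsed into one Man5-to-Man3 rule, since no intermediate species is
#' resolved in profiles), core fucosylation by Fut8, antenna extension by
#' Mgat2/4/5, galactosylation and sialylation.
#'
#' @param fut8_lock logical; if `TRUE` (default) Fut8 initiates a temporary
#'   lock (a hidden intermediate resolved at `lock_resolution_rate`) rather
#'   than adding the fucose instantly.  Setting `FALSE` gives the lock-free
#'   variant used to bound the lock artefact.
#' @return list of `enzyme_rule` objects, in pathway order.
#' @export
default_rules <- function(fut8_lock = TRUE) {
  list(
    make_rule("Man1",  "Man1",  c(man = -1L)),
    make_rule("Mgat1", "Mgat1", c(agn = +1L)),
    make_rule("Man2",  "Man2",  c(man = -2L)),
    make_rule("Fut8",  "Fut8",
              if (fut8_lock) c(locked = +1L) else c(fuc = +1L)),
    make_rule("Mgat2", "Mgat2", c(agn = +1L)),
    make_rule("Mgat4", "Mgat4", c(agn = +1L)),
    make_rule("Mgat5", "Mgat5", c(agn = +1L)),
    make_rule("GalT",  "GalT",  c(gal = +1L)),
    make_rule("SiaT",  "SiaT",  c(sia = +1L))
  )
}

LOCK_RESOLUTION_DELTAS <- c(locked = -1L, fuc = +1L)

#' Rules applicable to a state
#'
#' No ordinary rule fires on a locked state; only the lock-resolution
#' pseudo-reaction can (handled by the simulator, not listed here).
#'
#' @param state a valid `glycan_state`.
#' @param rules a rule list, e.g. [default_rules()].
#' @return the subset of `rules` whose guard holds.
#' @export
applicable_rules <- function(state, rules = default_rules()) {
  if (is_locked(state)) return(list())
  Filter(function(r) isTRUE(r$guard(unclass(state))), rules)
}

#' Enumerate all states reachable from a start state
#'
#' Breadth-first closure of `start` under the rule effects, including the
#' Fut8 lock intermediate and its resolution.  Used to build the transition
#' table driving the stochastic simulator and as a test oracle.
#'
#' @param rules a rule list.
#' @param start the entry state (default Man9, the species delivered to the
#'   Golgi after ER glucosidase trimming).
#' @return list of `glycan_state`s; the first element is `start`.
#' @export
enumerate_reachable_states <- function(rules = default_rules(),
                                       start = glycan_state(9L)) {
  seen <- new.env(parent = emptyenv())
  states <- list(start)
  assign(state_key(start), TRUE, envir = seen)
  queue <- list(start)
  while (length(queue)) {
    s <- queue[[1]]; queue <- queue[-1]
    succ <- list()
    if (is_locked(s)) {
      succ <- list(apply_deltas(s, LOCK_RESOLUTION_DELTAS))
    } else {
      for (r in applicable_rules(s, rules))
        succ <- c(succ, list(apply_deltas(s, r$deltas)))
    }
    for (ns in succ) {
      k <- state_key(ns)
      if (!exists(k, envir = seen, inherits = FALSE)) {
        assign(k, TRUE, envir = seen)
        states <- c(states, list(ns))
        queue <- c(queue, list(ns))
      }
    }
  }
  states
}

# Transition table over the reachable state set: one row per (state, rule)
# pair with the guard satisfied, plus lock-resolution rows (rule index
# n_rules + 1).  This indexed form is what the compiled SSA core consumes.
build_transition_table <- function(rules = default_rules(),
                                   start = glycan_state(9L)) {
  states <- enumerate_reachable_states(rules, start)
  keys <- vapply(states, state_key, character(1))
  idx <- setNames(seq_along(states), keys)
  n_rules <- length(rules)
  from <- integer(0); to <- integer(0); rule <- integer(0)
  for (i in seq_along(states)) {
    s <- states[[i]]
    if (is_locked(s)) {
      ns <- apply_deltas(s, LOCK_RESOLUTION_DELTAS)
      from <- c(from, i); to <- c(to, idx[[state_key(ns)]])
      rule <- c(rule, n_rules + 1L)
    } else {
      for (j in seq_len(n_rules)) {
        r <- rules[[j]]
        if (isTRUE(r$guard(unclass(s)))) {
          ns <- apply_deltas(s, r$deltas)
          from <- c(from, i); to <- c(to, idx[[state_key(ns)]])
          rule <- c(rule, j)
        }
      }
    }
  }
  locked_flag <- vapply(states, is_locked, logical(1))
  resolve_to <- seq_along(states)
  for (i in which(locked_flag))
    resolve_to[i] <- idx[[state_key(apply_deltas(states[[i]],
                                                 LOCK_RESOLUTION_DELTAS))]]
  names_unlocked <- rep(NA_character_, length(states))
  for (i in which(!locked_flag)) names_unlocked[i] <- canonical_name(states[[i]])
  list(states = states, keys = keys, locked = locked_flag,
       names = names_unlocked, resolve_to = resolve_to,
       transitions = data.frame(from = from, to = to, rule = rule),
       rule_names = c(vapply(rules, `[[`, character(1), "enzyme"),
                      "lock_resolution"),
       start_index = idx[[state_key(start)]])
}

#' Serialize a rule set to JSON
#'
#' Rules are stored as (enzyme name, guard predicate id, field deltas) so an
#' alternative topology can be configured by editing the document, as long as
#' its guards are drawn from the registered predicates.
#'
#' @param rules a rule list.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_rules_json <- function(rules, path) {
  doc <- lapply(rules, function(r)
    list(enzyme = r$enzyme, guard = r$guard_id, effect = as.list(r$deltas)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rule set from JSON
#'
#' @param path file written by [write_rules_json()] (or hand-edited).
#' @return a rule list.
#' @export
read_rules_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(doc, function(d) {
    deltas <- vapply(d$effect, function(x) as.integer(x), integer(1))
    make_rule(d$enzyme, d$guard, deltas)
  })
}
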