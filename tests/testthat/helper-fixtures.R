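# shared fixtures built in code

# minimal well-formed typed graph: A -> R1 -> B, closed by B -| R1
minimal_graph <- function() {
  typed_graph(
    substances = data.frame(id = c("A", "B")),
    reactions = data.frame(id = "R1"),
    edges = data.frame(
      source = c("A", "R1", "B"), target = c("R1", "B", "R1"),
      role = c("substrate", "product", "regulator"),
      sign = c("unknown", "unknown", "inhibition")))
}

# linear pathway of k substances closed by end-product inhibition,
# built explicitly (S1..Sk, R1..Rk; R1 regulated)
chain_contour_graph <- function(k) {
  subs <- sprintf("S%d", seq_len(k))
  reas <- sprintf("R%d", seq_len(k))
  edges <- data.frame(source = reas, target = subs, role = "product",
                      sign = "unknown", stringsAsFactors = FALSE)
  if (k > 1L) {
    edges <- rbind(edges, data.frame(
      source = subs[-k], target = reas[-1L], role = "substrate",
      sign = "unknown", stringsAsFactors = FALSE))
  }
  edges <- rbind(edges, data.frame(
    source = subs[k], target = reas[1L], role = "regulator",
    sign = "inhibition", stringsAsFactors = FALSE))
  typed_graph(substances = data.frame(id = subs),
              reactions = data.frame(id = reas), edges = edges)
}

damped_harmonic <- function(c = 0.2) {
  ode_system("damped_harmonic",
             function(t, y, p) c(y[2], -y[1] - p[["c"]] * y[2]),
             c(c = c), c(x = 1, v = 0), default_tend = 60)
}

constant_system <- function() {
  ode_system("constant", function(t, y, p) 0 * y, c(dummy = 1),
             c(x = 1), default_tend = 10)
}

# independent period oracle: local maxima located by discrete comparison
# plus quadratic interpolation, written independently of find_peaks
oracle_period <- function(times, x, discard_frac = 0.5) {
  keep <- times >= min(times) + discard_frac * (max(times) - min(times))
  t <- times[keep]; x <- x[keep]
  n <- length(x)
  pk_t <- c()
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1] &&
        x[i] > mean(x) + 0.1 * (max(x) - mean(x))) {
      a <- x[i - 1]; b <- x[i]; cc <- x[i + 1]
      shift <- 0.5 * (a - cc) / (a - 2 * b + cc)
      pk_t <- c(pk_t, t[i] + shift * (t[i + 1] - t[i]))
    }
  }
  if (length(pk_t) < 2) return(NA_real_)
  mean(diff(pk_t))
}

# minimal hand-written SBML (level 2) with one inhibited reaction
write_min_sbml <- function(path, modifier_sbo = "SBO:0000020") {
  sbo <- if (is.null(modifier_sbo)) "" else
    sprintf(' sboTerm="%s"', modifier_sbo)
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '  <model id="mini">',
    '    <listOfCompartments><compartment id="c"/></listOfCompartments>',
    '    <listOfSpecies>',
    '      <species id="A" name="substrate A" compartment="c"/>',
    '      <species id="B" compartment="c" boundaryCondition="true"/>',
    '    </listOfSpecies>',
    '    <listOfReactions>',
    '      <reaction id="R1">',
    '        <listOfReactants><speciesReference species="A"/></listOfReactants>',
    '        <listOfProducts><speciesReference species="B"/></listOfProducts>',
    '        <listOfModifiers>',
    sprintf('          <modifierSpeciesReference species="B"%s/>', sbo),
    '        </listOfModifiers>',
    '      </reaction>',
    '    </listOfReactions>',
    '  </model>',
    '</sbml>'), path)
  path
}
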