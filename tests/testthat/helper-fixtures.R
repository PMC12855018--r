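# In-code fixture builders shared by the unit tests.

# Minimal valid metabolite metadata.
toyMetaboliteMeta <- function(ids, formula = "C6H12O6",
                              cls = "carbohydrates") {
  data.frame(metabolite_id = ids, name = ids, formula = formula, cls = cls)
}

# Sample sheet for one tissue: groups x replicates.
toySampleMeta <- function(groups = GROUPS, reps = 4L, tissue = "liver") {
  sm <- expand.grid(replicate = seq_len(reps), group = groups,
                    stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_%s_r%d", tissue, sm$group, sm$replicate),
             tissue = tissue, group = sm$group, replicate = sm$replicate)
}

# Small single-tissue MetaboSet with given values (metabolites x samples).
toyMetaboSet <- function(values, groups = GROUPS, reps = 4L,
                         tissue = "liver", scale = "raw",
                         ids = sprintf("met%02d", seq_len(nrow(values)))) {
  MetaboSet(values, toySampleMeta(groups, reps, tissue),
            toyMetaboliteMeta(ids), scale = scale)
}

# A tiny linear network: labelled 2-carbon substrate A -> B -> sink, with an
# unlabelled dilution inflow into B.
toyLinearNetwork <- function() {
  parseNetwork(text = "
substrate Ain 0 0 1
substrate Din 1 0 0
reference R1
free R2
measured B
R1: Ain (ab) -> B (ab)
R2: Din (ab) -> B (ab)
R3: B (ab) -> Bout (ab)
")
}

# 3-carbon network with a symmetric intermediate whose scrambling is
# visible downstream: positions 1-2 of T are labelled, position 3 is not,
# and the symmetric pool S is split into a 1-carbon and a 2-carbon product.
# Hand solution: P = [0.5, 0.5], Q = [0, 0.5, 0.5].
toySymmetricNetwork <- function() {
  parseNetwork(text = "
substrate Ain 0 0 1
substrate Din 1 0
symmetric S
reference R1
measured P Q S
R1: Ain (ab) + Din (c) -> T (abc)
R2: T (abc) -> S (abc)
R3: S (abc) -> P (a) + Q (bc)
")
}

defaultTestFluxes <- c(V9 = 25, V11 = 40, V16 = 20)
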