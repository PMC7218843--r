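# Shared fixtures, memoised so expensive simulations run once per test file.

.fixtures <- new.env(parent = emptyenv())

getFixture <- function(name, make) {
  if (!exists(name, envir = .fixtures)) assign(name, make(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small but complete session: 8 sensors + acoustic, 2 stimuli x 6 trials
tinySession <- function() getFixture("tinySession", function()
  simulateSession(simConfig(nSensors = 8L, nTrialsPerStimulus = 6L,
                            nStimuli = 2L, seed = 123L)))

tinyProductionWindows <- function() getFixture("tinyProd", function() {
  sess <- tinySession()
  lapply(epochTrials(sess$recording), extractProductionWindow)
})

workedExample <- function() getFixture("workedExample", makeWorkedExample)

# deterministic binary label factor of length n
speechLabels <- function(runStart, runEnd, n) {
  l <- rep("NONSPEECH", n)
  l[runStart:runEnd] <- "SPEECH"
  factor(l, levels = c("SPEECH", "NONSPEECH"))
}
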