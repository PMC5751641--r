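# Default event schema: allowed roles per event type, roles that may be
# filled by events, and core roles (an event must keep at least one).
# Regulation-family types accept Theme + Cause with event-valued fillers;
# all other types accept an entity-valued Theme.
types:
  Cell_proliferation: {roles: [Theme], event_valued: [], core: [Theme]}
  Development: {roles: [Theme], event_valued: [], core: [Theme]}
  Blood_vessel_development: {roles: [Theme], event_valued: [], core: [Theme]}
  Growth: {roles: [Theme], event_valued: [], core: [Theme]}
  Death: {roles: [Theme], event_valued: [], core: [Theme]}
  Breakdown: {roles: [Theme], event_valued: [], core: [Theme]}
  Remodeling: {roles: [Theme], event_valued: [], core: [Theme]}
  Synthesis: {roles: [Theme], event_valued: [], core: [Theme]}
  Gene_expression: {roles: [Theme], event_valued: [], core: [Theme]}
  Transcription: {roles: [Theme], event_valued: [], core: [Theme]}
  Catabolism: {roles: [Theme], event_valued: [], core: [Theme]}
  Phosphorylation: {roles: [Theme], event_valued: [], core: [Theme]}
  Dephosphorylation: {roles: [Theme], event_valued: [], core: [Theme]}
  Localization: {roles: [Theme], event_valued: [], core: [Theme]}
  Binding: {roles: [Theme], event_valued: [], core: [Theme]}
  Planned_process: {roles: [Theme, Instrument], event_valued: [], core: [Theme]}
  Regulation: {roles: [Theme, Cause], event_valued: [Theme, Cause], core: [Theme]}
  Positive_regulation: {roles: [Theme, Cause], event_valued: [Theme, Cause], core: [Theme]}
  Negative_regulation: {roles: [Theme, Cause], event_valued: [Theme, Cause], core: [Theme]}
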