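[
  {
    "event_type": "birth",
    "triggers": ["born"],
    "patterns": {
      "time": "\\b(1[89][0-9]{2}|20[0-9]{2}|[a-z]+ years ago|\\d+ years ago)\\b",
      "location": "\\b(?:in|at|to) ([A-Z][a-z]+(?: [A-Z][a-z]+)?)(?=[ ,.]|$)",
      "participant": "\\b(?:with|married|met) ([A-Z][a-z]+(?: [A-Z][a-z]+)?)(?=[ ,.]|$)"
    }
  },
  {
    "event_type": "marriage",
    "triggers": ["married", "wedding"],
    "patterns": {
      "time": "\\b(1[89][0-9]{2}|20[0-9]{2}|[a-z]+ years ago|\\d+ years ago)\\b",
      "location": "\\b(?:in|at|to) ([A-Z][a-z]+(?: [A-Z][a-z]+)?)(?=[ ,.]|$)",
      "participant": "\\b(?:with|married|met) ([A-Z][a-z]+(?: [A-Z][a-z]+)?)(?=[ ,.]|$)"
    }
  },
  {
    "event_type": "career",
    "triggers": ["worked", "job"],
    "patterns": {
      "time": "\\b(1[89][0-9]{2}|20[0-9]{2}|[a-z]+ years ago|\\d+ years ago)\\b",
      "location": "\\b(?:in|at|to) ([A-Z][a-z]+(?: [A-Z][a-z]+)?)(?=[ ,.]|$)"
    }
  }
]
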