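# Generic structured-interview prompts, one per line.
how have you been feeling over the past week
how has your sleep been lately
how is your appetite have you been eating well
can you tell me about your mood recently
do you ever hear voices or sounds that other people cannot hear
do you ever see things that other people cannot see
do you feel that people are trying to harm you or follow you
do you believe you have special powers or abilities that others do not have
how have you been getting along with your family and friends
how do you usually spend your day
is there anything that has been worrying you lately
do you feel that your thoughts are being controlled or interfered with
how would you describe your energy level these days
have you had any trouble concentrating or keeping your thoughts together
is there anything else you would like to tell me about how you have been doing
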