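"sample","event","side"
100,"IC","L"
111,"TC","R"
155,"IC","R"
166,"TC","L"
210,"IC","L"
221,"TC","R"
265,"IC","R"
276,"TC","L"
320,"IC","L"
331,"TC","R"
375,"IC","R"
386,"TC","L"
430,"IC","L"
441,"TC","R"
485,"IC","R"
496,"TC","L"
540,"IC","L"
551,"TC","R"
595,"IC","R"
606,"TC","L"
650,"IC","L"
661,"TC","R"
705,"IC","R"
716,"TC","L"
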